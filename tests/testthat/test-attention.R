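# The FSCA block and its baselines: hand-computed pooling/gating oracles,
# shape preservation, gate range, and identity behavior when the gates are
# forced open.

test_that("directional stage reproduces the hand-computed pooling oracle", {
  # 2x2 single-channel input with all internal transforms set to identity:
  # row means (2, 6), column means (3, 5), y[i,j] = x[i,j]*sig(row_i)*sig(col_j)
  x <- array(c(1, 5, 3, 7), dim = c(2, 2, 1, 1))  # x[1,] = (1,3); x[2,] = (5,7)
  m <- identity_fsca_spatial(1L)
  y <- m$forward(leafmfs:::ag_input(x), training = FALSE)$data
  row_means <- c(2, 6)
  col_means <- c(3, 5)
  want <- x
  for (i in 1:2) for (j in 1:2) {
    want[i, j, 1, 1] <- x[i, j, 1, 1] * sigmoid(row_means[i]) * sigmoid(col_means[j])
  }
  expect_equal(y, want, tolerance = 1e-6)
  expect_equal(y[1, 1, 1, 1], 1 * sigmoid(2) * sigmoid(3), tolerance = 1e-6)
})

test_that("directional stage is equivariant to transposing the two axes", {
  set.seed(21)
  for (C in c(1L, 3L)) {
    m <- identity_fsca_spatial(C)
    x <- rand_fmap(5, 8, C, 2)
    y <- m$forward(leafmfs:::ag_input(x), training = FALSE)$data
    xt <- aperm(x, c(2, 1, 3, 4))
    yt <- m$forward(leafmfs:::ag_input(xt), training = FALSE)$data
    expect_equal(aperm(yt, c(2, 1, 3, 4)), y, tolerance = 1e-10)
  }
})

test_that("cross-channel stage reproduces the max/mean fusion oracle", {
  # C = 2, x[1,1,] = (1,3): max 3, mean 2; 1x1 fusing conv with weights
  # (0.5, 0.5) and zero bias gives gate sig(2.5) at that location.
  set.seed(2)
  cfg <- attention_config(spatial_kernel = 1L)
  m <- leafmfs:::mod_fsca_channel(2L, cfg, "ch")
  m$params[["ch.fuse.w"]]$data <- array(c(0.5, 0.5), dim = c(1, 1, 2, 1))
  m$params[["ch.fuse.b"]]$data <- 0
  x <- rand_fmap(3, 3, 2, 1)
  x[1, 1, , 1] <- c(1, 3)
  y <- m$forward(leafmfs:::ag_input(x), training = FALSE)$data
  g11 <- sigmoid(0.5 * 3 + 0.5 * 2)
  expect_equal(y[1, 1, , 1], x[1, 1, , 1] * g11, tolerance = 1e-10)
  # gate is shared across channels
  g <- y / x
  expect_equal(g[, , 1, 1], g[, , 2, 1], tolerance = 1e-10)
})

test_that("cross-channel pooling degenerates correctly for a single channel", {
  set.seed(4)
  x <- rand_fmap(4, 5, 1, 1)
  xn <- leafmfs:::ag_input(x)
  mx <- leafmfs:::ag_chan_max(xn)$data
  mn <- leafmfs:::ag_chan_mean(xn)$data
  expect_equal(mx, x)
  expect_equal(mn, x)
})

test_that("every attention block preserves shape and keeps gates in (0,1)", {
  set.seed(31)
  blocks <- c("se", "eca", "cbam", "ca", "fsca", "none")
  shapes <- cbind(
    h = sample(1:32, 6, replace = TRUE),
    w = sample(1:32, 6, replace = TRUE),
    c = sample(1:64, 6, replace = TRUE)
  )
  for (nm in blocks) {
    for (r in seq_len(nrow(shapes))) {
      C <- shapes[r, "c"]
      m <- attention_block(nm, C)
      x <- rand_fmap(shapes[r, "h"], shapes[r, "w"], C, 2)
      y <- apply_module(m, x)
      expect_identical(dim(y), dim(x))
      # sigmoid gating can only shrink magnitudes
      if (nm != "none") {
        expect_true(all(abs(y) <= abs(x) + 1e-12),
                    label = paste(nm, "gate range bound"))
      }
    }
  }
})

test_that("forcing every gate to one reproduces the input exactly", {
  set.seed(41)
  for (nm in c("se", "eca", "cbam", "ca", "fsca")) {
    C <- 12L
    m <- attention_block(nm, C)
    leafmfs:::force_gates(m, TRUE)
    x <- rand_fmap(9, 7, C, 2)
    y <- apply_module(m, x)
    expect_equal(y, x, tolerance = 1e-6)
  }
})

test_that("CBAM gating is spatially uniform on constant input", {
  set.seed(51)
  m <- attention_block("cbam", 8L)
  x <- array(5, dim = c(16, 16, 8, 1))
  y <- apply_module(m, x)
  # constant input: average and max pooling coincide (the two MLP branches
  # are identical) and both gates are constant over space away from the
  # zero-padded border of the 7x7 spatial fuse, so each channel's interior
  # is scaled by a single factor
  interior <- 4:13
  for (c in 1:8) {
    yc <- y[interior, interior, c, 1]
    expect_equal(max(yc) - min(yc), 0, tolerance = 1e-12)
  }
  # sigmoid gating keeps the scaling strictly inside (0, input)
  expect_true(all(y > 0 & y < 5))
})

test_that("squeeze-excitation parameter count follows the analytic formula", {
  C <- 64L; r <- 4L
  m <- attention_block("se", C, attention_config(reduction_ratio = r))
  sq <- leafmfs:::make_divisible(C %/% r, 8L)
  expect_equal(leafmfs:::module_param_count(m), C * sq + sq + sq * C + C)
})

test_that("fused block applies the directional stage then the channel stage", {
  set.seed(61)
  C <- 6L
  cfg <- attention_config(reduction_ratio = 1L, min_reduced_channels = 1L,
                          act = "identity")
  m <- attention_block("fsca", C, cfg)
  x <- rand_fmap(5, 5, C, 1)
  sp <- m$children[[1]]
  chn <- m$children[[2]]
  y_manual <- chn$forward(sp$forward(leafmfs:::ag_input(x), FALSE), FALSE)$data
  y <- apply_module(m, x)
  expect_equal(y, y_manual, tolerance = 1e-12)
  # and the order flag swaps the composition
  cfg2 <- attention_config(order = "channel_first")
  m2 <- attention_block("fsca", C, cfg2)
  expect_equal(m2$children[[1]]$prefix, "fsca.channel")
})

test_that("unknown attention names are rejected", {
  expect_error(attention_block("swin", 8L), "unknown attention")
})
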