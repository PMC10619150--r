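# Model assembly and accounting: bottleneck structure, the v3-Large
# baseline's exact parameter total, MAC conventions, and the
# baseline-recovery identity of the MFS variant.

test_that("bottleneck parameter count matches the analytic hand count", {
  # no expansion (16 = 16), k = 3, no attention: depthwise 3*3*16 + bn 2*16
  # + project 16*16 + bn 2*16 = 464
  b <- build_bottleneck(bottleneck_spec(16, 16, 16, kernel = 3, stride = 1,
                                        activation = "relu"))
  expect_equal(leafmfs:::module_param_count(b), 464)
})

test_that("residual connection follows the stride/width invariant", {
  set.seed(91)
  # stride 1 + equal widths: residual present (zero weights give y == x)
  b <- build_bottleneck(bottleneck_spec(8, 16, 8, stride = 1))
  for (nm in names(b$params)) b$params[[nm]]$data[] <- 0
  x <- rand_fmap(6, 6, 8, 1)
  y <- b$forward(leafmfs:::ag_input(x), training = FALSE)$data
  expect_equal(y, x)
  # stride 2: no residual regardless of widths, and ceil(H/2) output
  b2 <- build_bottleneck(bottleneck_spec(8, 16, 8, stride = 2))
  for (nm in names(b2$params)) b2$params[[nm]]$data[] <- 0
  y2 <- b2$forward(leafmfs:::ag_input(rand_fmap(7, 9, 8, 1)),
                   training = FALSE)$data
  expect_identical(dim(y2)[1:2], c(4L, 5L))
  expect_equal(max(abs(y2)), 0)
})

test_that("v3-Large parameter totals match the layer-by-layer oracle", {
  expect_identical(count_params(build_mobilenet_v3_large(1000)), 5483032)
  m9 <- build_mobilenet_v3_large(9)
  expect_identical(count_params(m9), 4213561)
  # swapping the classifier head accounts for the whole difference
  expect_identical(5483032 - (1280 * 1000 + 1000) + (1280 * 9 + 9), 4213561)
  # the count is the sum of per-stage counts (oracle equivalence per block)
  tab <- model_layer_table(m9)
  expect_equal(sum(tab$params), 4213561)
})

test_that("parameter count is independent of input size, MACs are not", {
  m <- build_model(spec_mfs_compact(5, input_size = 64L))
  p1 <- count_params(m)
  expect_identical(p1, count_params(m))
  m96 <- count_macs(m, c(96L, 96L))
  m48 <- count_macs(m, c(48L, 48L))
  expect_gt(m96, m48)
})

test_that("MAC accounting follows the stated convention", {
  # 1x1 conv 3 -> 8 on 4x4 input: 4*4*8*3 = 384 MACs, 24 weights
  conv <- leafmfs:::mod_conv2d(3L, 8L, 1L)
  g <- conv$macs_fn(4, 4)
  expect_equal(g$macs, 384)
  expect_equal(leafmfs:::module_param_count(conv), 24)
  # doubling H and W quadruples convolutional MACs (attention-free model:
  # SE's fully connected layers cost the same at any resolution)
  m <- build_mobilenet_mfs(9, frontend = NULL, attention = "none")
  conv_macs <- function(hw) {
    h <- hw; w <- hw; total <- 0
    for (s in m$stages) {
      gg <- s$macs_fn(h, w); h <- gg$h; w <- gg$w; total <- total + gg$macs
    }
    total
  }
  # power-of-two sizes keep every strided halving exact
  expect_equal(conv_macs(256) / conv_macs(128), 4, tolerance = 1e-12)
})

test_that("v3-Large MACs at 224 land within 15% of the published figure", {
  m <- build_mobilenet_v3_large(9)
  mflops <- count_macs(m, c(224L, 224L)) / 1e6
  expect_lt(abs(mflops - 226.44) / 226.44, 0.15)
})

test_that("MFS with frontend off and SE attention recovers the baseline", {
  base <- build_mobilenet_v3_large(9)
  rec <- build_mobilenet_mfs(9, frontend = NULL, attention = "se")
  expect_identical(count_params(rec), count_params(base))
  tb <- model_layer_table(base); tr <- model_layer_table(rec)
  expect_equal(tr$params, tb$params)
  expect_equal(tr$macs, tb$macs)
})

test_that("forward pass emits one logit per class and is deterministic", {
  set.seed(101)
  m <- build_mobilenet_mfs(9)
  x <- rand_fmap(64, 64, 3, 1)
  s1 <- predict_scores(m, x)
  s2 <- predict_scores(m, x)
  expect_identical(nrow(s1$logits), 9L)
  expect_identical(s1$logits, s2$logits)
  expect_equal(colSums(s1$probs), 1, tolerance = 1e-12)
})

test_that("channel-chain violations and bad specs are rejected", {
  bad <- list(bottleneck_spec(16, 32, 24), bottleneck_spec(32, 64, 32))
  expect_error(model_spec(bad, 9), "input channels")
  expect_error(bottleneck_spec(8, 16, 8, stride = 3), "stride")
  expect_error(bottleneck_spec(8, 16, 8, kernel = 4), "odd")
  expect_error(model_spec(list(bottleneck_spec(16, 32, 24)), 1), "num_classes")
})

test_that("MFS default parameter count sits between compact and baseline", {
  mfs <- build_mobilenet_mfs(9)
  p <- count_params(mfs)
  # FSCA is far cheaper than SE, so the default MFS variant is lighter than
  # the SE baseline; the front end adds back a little
  expect_lt(p, count_params(build_mobilenet_v3_large(9)))
  expect_gt(p, 2.5e6)
})
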