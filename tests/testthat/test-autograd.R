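# Correctness of the differentiation engine: kernel outputs against an
# independent direct-summation oracle, and analytic gradients against
# central finite differences through every layer type.

test_that("convolution kernels match the direct-summation oracle", {
  set.seed(11)
  cases <- list(
    c(k = 3, s = 1, p = 1, g = 1),  # dense, direct path
    c(k = 1, s = 1, p = 0, g = 1),  # pointwise fast path
    c(k = 5, s = 2, p = 2, g = 1),  # strided
    c(k = 3, s = 1, p = 1, g = 4),  # depthwise-style groups
    c(k = 7, s = 1, p = 3, g = 1)   # large kernel
  )
  for (cs in cases) {
    C <- 4L; Cout <- 8L
    k <- as.integer(cs[["k"]]); s <- as.integer(cs[["s"]])
    p <- as.integer(cs[["p"]]); g <- as.integer(cs[["g"]])
    x <- rand_fmap(9, 8, C, 2)
    w <- array(rnorm(k^2 * (C / g) * Cout), dim = c(k, k, C / g, Cout))
    b <- rnorm(Cout)
    got <- leafmfs:::conv2d_fwd_cpp(x, w, b, s, p, g)
    want <- naive_conv2d(x, w, b, s, p, g)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences through a full model", {
  set.seed(7)
  model <- build_model(spec_mfs_compact(3, input_size = 16L))
  x <- rand_fmap(16, 16, 3, 2)
  y <- c(1L, 3L)
  snap <- lapply(model$states, function(s) list(m = s$mean, v = s$var))
  reset_states <- function() {
    for (nm in names(model$states)) {
      model$states[[nm]]$mean <- snap[[nm]]$m
      model$states[[nm]]$var <- snap[[nm]]$v
    }
  }
  loss_at <- function() {
    leafmfs:::ag_tape_start()
    lg <- model$forward(leafmfs:::ag_input(x), training = TRUE)
    l <- leafmfs:::ag_softmax_xent(lg, y)
    leafmfs:::ag_backward(l)
    leafmfs:::ag_tape_stop()
    l$data
  }
  loss_at()
  grads <- lapply(model$params, function(p) p$grad)
  reset_states()
  # one element from every kind of layer: stem conv, frontend branch,
  # FSCA reduce / fuse bias, depthwise, bn scale, classifier
  sel <- c("stem.conv.w", "frontend.branch4.conv.w",
           "bneck01.att.spatial.reduce.w", "bneck01.att.channel.fuse.b",
           "bneck03.dw.conv.w", "bneck02.expand.bn.gamma",
           "head.classifier.w")
  eps <- 1e-5
  for (nm in sel) {
    p <- model$params[[nm]]
    i <- sample(length(p$data), 1L)
    old <- p$data[i]
    for (q in model$params) q$grad <- NULL
    p$data[i] <- old + eps; lp <- loss_at(); reset_states()
    for (q in model$params) q$grad <- NULL
    p$data[i] <- old - eps; lm <- loss_at(); reset_states()
    p$data[i] <- old
    expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("broadcast multiply handles all gate geometries", {
  set.seed(3)
  x <- rand_fmap(5, 4, 6, 2)
  for (gd in list(c(1, 1, 6, 2), c(5, 1, 6, 2), c(1, 4, 6, 2),
                  c(5, 4, 1, 2), c(1, 1, 1, 1))) {
    g <- array(runif(prod(gd)), dim = gd)
    got <- leafmfs:::bcast_mul_fwd_cpp(x, g)
    want <- x * leafmfs:::bcast_expand(g, dim(x))
    expect_equal(got, want, tolerance = 1e-14)
    dy <- rand_fmap(5, 4, 6, 2)
    gr <- leafmfs:::bcast_mul_bwd_cpp(x, g, dy)
    expect_equal(gr$dx, dy * leafmfs:::bcast_expand(g, dim(x)),
                 tolerance = 1e-14)
    expect_equal(gr$dg, leafmfs:::reduce_bcast(dy * x, gd),
                 tolerance = 1e-12)
  }
})

test_that("softmax cross-entropy matches a direct computation", {
  set.seed(5)
  z <- matrix(rnorm(4 * 6), 4, 6)
  y <- sample(4, 6, replace = TRUE)
  leafmfs:::ag_tape_start()
  node <- leafmfs:::ag_input(z)
  l <- leafmfs:::ag_softmax_xent(node, y)
  leafmfs:::ag_backward(l)
  leafmfs:::ag_tape_stop()
  p <- apply(z, 2, function(col) exp(col) / sum(exp(col)))
  expect_equal(l$data, -mean(log(p[cbind(y, 1:6)])), tolerance = 1e-12)
  onehot <- matrix(0, 4, 6); onehot[cbind(y, 1:6)] <- 1
  expect_equal(node$grad, (p - onehot) / 6, tolerance = 1e-12)
})
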