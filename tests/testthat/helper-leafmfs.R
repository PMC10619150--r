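# Shared fixtures and identity-configuration helpers.

rand_fmap <- function(h, w, c, n = 1L) {
  array(rnorm(h * w * c * n), dim = c(h, w, c, n))
}

# Reference convolution by direct summation (independent of the package's
# kernels; used as the oracle for conv correctness).
naive_conv2d <- function(x, w, b, stride, pad, groups) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]; Cg <- dim(w)[3]; Cout <- dim(w)[4]; Og <- Cout / groups
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + (1:H), pad + (1:W), , ] <- x
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% Og
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- 0
      for (c in 1:Cg) for (kh in 1:k) for (kw in 1:k) {
        acc <- acc + xp[(ho - 1) * stride + kh, (wo - 1) * stride + kw,
                        g * Cg + c, n] * w[kh, kw, c, co]
      }
      out[ho, wo, co, n] <- acc + b[co]
    }
  }
  out
}

# Set a 1x1 convolution's weight to the identity map on C channels.
set_identity_conv1x1 <- function(m, name, C) {
  w <- array(0, dim = c(1, 1, C, C))
  for (c in seq_len(C)) w[1, 1, c, c] <- 1
  m$params[[paste0(name, ".w")]]$data <- w
  bn <- paste0(name, ".b")
  if (!is.null(m$params[[bn]])) m$params[[bn]]$data <- numeric(C)
  invisible(m)
}

# Make a batch-norm exactly the identity in inference mode: running mean 0,
# running var 1, gamma = sqrt(1 + eps) cancels the normalization factor.
set_identity_bn <- function(m, name, C, eps = 1e-5) {
  m$params[[paste0(name, ".gamma")]]$data <- rep(sqrt(1 + eps), C)
  m$params[[paste0(name, ".beta")]]$data <- rep(0, C)
  st <- m$states[[name]]
  st$mean <- rep(0, C)
  st$var <- rep(1, C)
  invisible(m)
}

# FSCA directional stage configured so every internal transform is the
# identity (reduction 1, identity activation, identity convolutions and
# batch norm): the output depends only on pooling and the sigmoid gates.
identity_fsca_spatial <- function(C, prefix = "sp") {
  cfg <- attention_config(reduction_ratio = 1L, min_reduced_channels = 1L,
                          act = "identity")
  m <- leafmfs:::mod_fsca_spatial(C, cfg, prefix)
  set_identity_conv1x1(m, paste0(prefix, ".reduce"), C)
  set_identity_bn(m, paste0(prefix, ".bn"), C)
  set_identity_conv1x1(m, paste0(prefix, ".expand_h"), C)
  set_identity_conv1x1(m, paste0(prefix, ".expand_w"), C)
  m
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Tiny synthetic data bundle for smoke training runs (images in memory,
# no files touched).
tiny_synthetic_data <- function(n_per_class = 10L, image_size = 48L,
                                seed = 1L, test_frac = 0.2) {
  spec <- synthetic_spec(n_per_class = n_per_class, image_size = image_size,
                         seed = seed)
  imgs <- generate_synthetic_images(spec)
  classes <- names(imgs)
  n_tot <- n_per_class * length(classes)
  x <- array(0, dim = c(image_size, image_size, 3L, n_tot))
  y <- integer(n_tot)
  i <- 0L
  for (k in seq_along(classes)) {
    for (r in imgs[[classes[k]]]) {
      i <- i + 1L
      img <- r$img
      for (c in 1:3) {
        img[, , c] <- (img[, , c] - c(0.485, 0.456, 0.406)[c]) /
          c(0.229, 0.224, 0.225)[c]
      }
      x[, , , i] <- img
      y[i] <- k
    }
  }
  n_test <- max(1L, round(test_frac * n_per_class))
  test_idx <- as.vector(vapply(seq_along(classes) - 1L, function(k) {
    k * n_per_class + seq_len(n_test)
  }, integer(n_test)))
  list(
    train = list(x = x[, , , -test_idx, drop = FALSE], y = y[-test_idx],
                 classes = classes),
    test = list(x = x[, , , test_idx, drop = FALSE], y = y[test_idx],
                classes = classes)
  )
}
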