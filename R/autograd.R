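## Reverse-mode automatic differentiation over a linear tape.
##
## Feature maps are numeric arrays laid out (H, W, C, N); pooled feature
## vectors are (C, N) matrices. Nodes are environments carrying $data and,
## after a backward pass, $grad. Ops append themselves to a tape when
## recording is on; ag_backward() replays the tape in reverse.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- vector("list", 0L)
.ag$ntape <- 0L

ag_node <- function(data, backward = NULL, name = NULL) {
  n <- new.env(parent = emptyenv())
  n$data <- data
  n$grad <- NULL
  n$name <- name
  if (isTRUE(.ag$recording) && !is.null(backward)) {
    n$backward <- backward
    k <- .ag$ntape + 1L
    .ag$ntape <- k
    if (k > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", 256L))
    .ag$tape[[k]] <- n
  }
  n
}

#' @keywords internal
ag_param <- function(data, name = NULL) {
  n <- new.env(parent = emptyenv())
  n$data <- data
  n$grad <- NULL
  n$name <- name
  n$frozen <- FALSE
  class(n) <- "ag_param"
  n
}

ag_input <- function(data) ag_node(data)

ag_tape_start <- function() {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 256L)
  .ag$ntape <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- vector("list", 0L)
  .ag$ntape <- 0L
  invisible(NULL)
}

with_tape <- function(expr) {
  ag_tape_start()
  on.exit(ag_tape_stop())
  force(expr)
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

## Backpropagate from a scalar loss node through the recorded tape.
ag_backward <- function(loss) {
  if (!isTRUE(.ag$recording)) stop("ag_backward() requires an active tape")
  loss$grad <- array(1, dim = dim_of(loss$data))
  if (length(loss$data) == 1L) loss$grad <- 1
  for (i in seq(.ag$ntape, 1L)) {
    n <- .ag$tape[[i]]
    if (!is.null(n$grad)) n$backward(n)
  }
  invisible(NULL)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

## --- broadcasting helpers -------------------------------------------------

## Expand an array with singleton dims up to `dims` by index replication.
bcast_expand <- function(g, dims) {
  dg <- dim(g)
  if (identical(dg, dims)) return(g)
  idx <- lapply(seq_along(dims), function(k) {
    if (dg[k] == 1L && dims[k] > 1L) rep.int(1L, dims[k]) else seq_len(dims[k])
  })
  out <- g[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
  dim(out) <- dims
  out
}

## Sum `t` (full dims) down to target dims (subset of axes are 1).
reduce_bcast <- function(t, target) {
  d <- dim(t)
  for (ax in seq_along(target)) {
    if (target[ax] == 1L && d[ax] > 1L) {
      t <- sum_axis(t, ax)
      d <- dim(t)
    }
  }
  t
}

## Sum a 4-d array over one axis, keeping the axis with extent 1.
sum_axis <- function(x, ax) {
  d <- dim(x)
  if (ax == 1L) {
    m <- matrix(x, nrow = d[1])
    out <- colSums(m)
    dim(out) <- c(1L, d[2], d[3], d[4])
  } else if (ax == 4L) {
    m <- matrix(x, ncol = d[4])
    out <- rowSums(m)
    dim(out) <- c(d[1], d[2], d[3], 1L)
  } else if (ax == 2L) {
    p <- aperm(x, c(1L, 3L, 4L, 2L))
    m <- matrix(p, ncol = d[2])
    out <- rowSums(m)
    dim(out) <- c(d[1], d[3], d[4], 1L)
    out <- aperm(out, c(1L, 4L, 2L, 3L))
  } else {
    p <- aperm(x, c(1L, 2L, 4L, 3L))
    m <- matrix(p, ncol = d[3])
    out <- rowSums(m)
    dim(out) <- c(d[1], d[2], d[4], 1L)
    out <- aperm(out, c(1L, 2L, 4L, 3L))
  }
  out
}

## --- elementwise ops ------------------------------------------------------

ag_relu <- function(x) {
  y <- x$data * (x$data > 0)
  ag_node(y, backward = function(n) acc_grad(x, n$grad * (x$data > 0)))
}

hswish_raw <- function(v) v * pmin(pmax(v + 3, 0), 6) / 6
hsigmoid_raw <- function(v) pmin(pmax(v + 3, 0), 6) / 6

ag_hswish <- function(x) {
  v <- x$data
  ag_node(hswish_fwd_cpp(v), backward = function(n) {
    acc_grad(x, hswish_bwd_cpp(v, n$grad))
  })
}

ag_hsigmoid <- function(x) {
  v <- x$data
  y <- hsigmoid_raw(v)
  ag_node(y, backward = function(n) {
    d <- (v > -3 & v < 3) / 6
    acc_grad(x, n$grad * d)
  })
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$data))
  ag_node(s, backward = function(n) acc_grad(x, n$grad * s * (1 - s)))
}

ag_identity_act <- function(x) x

activation_fn <- function(name) {
  switch(name,
    relu = ag_relu,
    hswish = ag_hswish,
    hsigmoid = ag_hsigmoid,
    sigmoid = ag_sigmoid,
    identity = ag_identity_act,
    stop("unknown activation: ", name)
  )
}

ag_add <- function(a, b) {
  ag_node(a$data + b$data, backward = function(n) {
    acc_grad(a, n$grad)
    acc_grad(b, n$grad)
  })
}

## y = x * g with g broadcast over singleton axes.
ag_mul <- function(x, g) {
  y <- bcast_mul_fwd_cpp(x$data, g$data)
  ag_node(y, backward = function(n) {
    gr <- bcast_mul_bwd_cpp(x$data, g$data, n$grad)
    acc_grad(x, gr$dx)
    acc_grad(g, gr$dg)
  })
}

## --- pooling --------------------------------------------------------------

## Global average pool (H,W,C,N) -> (C,N).
ag_gap <- function(x) {
  d <- dim(x$data)
  m <- matrix(x$data, nrow = d[1] * d[2])
  y <- matrix(colMeans(m), nrow = d[3], ncol = d[4])
  ag_node(y, backward = function(n) {
    g <- array(rep(as.vector(n$grad) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    acc_grad(x, g)
  })
}

## Global max pool (H,W,C,N) -> (C,N).
ag_gmp <- function(x) {
  d <- dim(x$data)
  m <- matrix(x$data, nrow = d[1] * d[2])
  idx <- max.col(t(m), ties.method = "first")
  y <- matrix(m[cbind(idx, seq_len(ncol(m)))], nrow = d[3], ncol = d[4])
  ag_node(y, backward = function(n) {
    g <- array(0, dim = d)
    gm <- matrix(g, nrow = d[1] * d[2])
    gm[cbind(idx, seq_len(ncol(gm)))] <- as.vector(n$grad)
    dim(gm) <- d
    acc_grad(x, gm)
  })
}

## Mean over the width axis, keepdim: (H,W,C,N) -> (H,1,C,N).
ag_mean_w <- function(x) {
  d <- dim(x$data)
  p <- aperm(x$data, c(1L, 3L, 4L, 2L))
  y <- rowMeans(matrix(p, ncol = d[2]))
  dim(y) <- c(d[1], 1L, d[3], d[4])
  ag_node(y, backward = function(n) {
    acc_grad(x, bcast_expand(n$grad / d[2], d))
  })
}

## Mean over the height axis, keepdim: (H,W,C,N) -> (1,W,C,N).
ag_mean_h <- function(x) {
  d <- dim(x$data)
  y <- colMeans(matrix(x$data, nrow = d[1]))
  dim(y) <- c(1L, d[2], d[3], d[4])
  ag_node(y, backward = function(n) {
    acc_grad(x, bcast_expand(n$grad / d[1], d))
  })
}

## Mean over channels, keepdim: (H,W,C,N) -> (H,W,1,N).
ag_chan_mean <- function(x) {
  d <- dim(x$data)
  p <- aperm(x$data, c(1L, 2L, 4L, 3L))
  y <- rowMeans(matrix(p, ncol = d[3]))
  dim(y) <- c(d[1], d[2], 1L, d[4])
  ag_node(y, backward = function(n) {
    acc_grad(x, bcast_expand(n$grad / d[3], d))
  })
}

## Max over channels, keepdim: (H,W,C,N) -> (H,W,1,N).
ag_chan_max <- function(x) {
  d <- dim(x$data)
  p <- aperm(x$data, c(1L, 2L, 4L, 3L))
  m <- matrix(p, ncol = d[3])
  idx <- max.col(m, ties.method = "first")
  y <- m[cbind(seq_len(nrow(m)), idx)]
  dim(y) <- c(d[1], d[2], 1L, d[4])
  ag_node(y, backward = function(n) {
    gm <- matrix(0, nrow = nrow(m), ncol = d[3])
    gm[cbind(seq_len(nrow(m)), idx)] <- as.vector(n$grad)
    dim(gm) <- c(d[1], d[2], d[4], d[3])
    acc_grad(x, aperm(gm, c(1L, 2L, 4L, 3L)))
  })
}

## --- structural ops -------------------------------------------------------

ag_concat <- function(nodes, axis) {
  dims <- lapply(nodes, function(n) dim(n$data))
  ext <- vapply(dims, function(d) d[axis], integer(1))
  dout <- dims[[1]]
  dout[axis] <- sum(ext)
  out <- array(0, dim = dout)
  ends <- cumsum(ext)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (i in seq_along(nodes)) {
    r <- starts[i]:ends[i]
    if (axis == 2L) out[, r, , ] <- nodes[[i]]$data
    else if (axis == 3L) out[, , r, ] <- nodes[[i]]$data
    else stop("unsupported concat axis")
  }
  ag_node(out, backward = function(n) {
    for (i in seq_along(nodes)) {
      r <- starts[i]:ends[i]
      g <- if (axis == 2L) n$grad[, r, , , drop = FALSE] else n$grad[, , r, , drop = FALSE]
      acc_grad(nodes[[i]], g)
    }
  })
}

ag_slice <- function(x, axis, from, to) {
  d <- dim(x$data)
  r <- from:to
  y <- if (axis == 2L) x$data[, r, , , drop = FALSE] else x$data[, , r, , drop = FALSE]
  ag_node(y, backward = function(n) {
    g <- array(0, dim = d)
    if (axis == 2L) g[, r, , ] <- n$grad else g[, , r, ] <- n$grad
    acc_grad(x, g)
  })
}

ag_permute <- function(x, perm) {
  inv <- order(perm)
  ag_node(aperm(x$data, perm), backward = function(n) {
    acc_grad(x, aperm(n$grad, inv))
  })
}

## --- parameterized ops ----------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  bias <- if (is.null(b)) numeric(0) else b$data
  y <- conv2d_fwd_cpp(x$data, w$data, bias, as.integer(stride), as.integer(pad),
                      as.integer(groups))
  ag_node(y, backward = function(n) {
    gr <- conv2d_bwd_cpp(x$data, w$data, n$grad, as.integer(stride),
                         as.integer(pad), as.integer(groups), !is.null(b))
    acc_grad(x, gr$dx)
    acc_grad(w, gr$dw)
    if (!is.null(b)) acc_grad(b, gr$db)
  })
}

## Batch norm over (H,W,N) per channel; `state` holds running moments.
ag_bn2d <- function(x, gamma, beta, state, training = FALSE, momentum = 0.1,
                    eps = 1e-5) {
  if (training) {
    mo <- bn_moments_cpp(x$data)
    mu <- mo$mean; va <- mo$var
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean; va <- state$var
  }
  y <- bn_fwd_cpp(x$data, gamma$data, beta$data, mu, va, eps)
  ag_node(y, backward = function(n) {
    gr <- bn_bwd_cpp(x$data, n$grad, gamma$data, mu, va, eps, training)
    acc_grad(x, gr$dx)
    acc_grad(gamma, gr$dgamma)
    acc_grad(beta, gr$dbeta)
  })
}

## Dense layer on (C_in, N) features: y = W x + b, W is (C_out, C_in).
ag_dense <- function(x, w, b = NULL) {
  y <- w$data %*% x$data
  if (!is.null(b)) y <- y + b$data
  ag_node(y, backward = function(n) {
    acc_grad(x, crossprod(w$data, n$grad))
    acc_grad(w, tcrossprod(n$grad, x$data))
    if (!is.null(b)) acc_grad(b, rowSums(n$grad))
  })
}

## 1-d convolution along the channel axis of (C,N) features (ECA-style),
## zero-padded to "same" length. w is a length-k vector, b a scalar or NULL.
ag_conv1d_channels <- function(x, w, b = NULL) {
  v <- x$data
  C <- nrow(v); k <- length(w$data); pad <- (k - 1L) %/% 2L
  shift_rows <- function(m, s) {
    ## rows move by s; vacated rows zero
    out <- matrix(0, nrow(m), ncol(m))
    if (s >= 0) {
      if (s < nrow(m)) out[(1 + s):nrow(m), ] <- m[1:(nrow(m) - s), , drop = FALSE]
    } else {
      s <- -s
      if (s < nrow(m)) out[1:(nrow(m) - s), ] <- m[(1 + s):nrow(m), , drop = FALSE]
    }
    out
  }
  y <- matrix(0, C, ncol(v))
  for (j in seq_len(k)) y <- y + w$data[j] * shift_rows(v, pad - (j - 1L))
  if (!is.null(b)) y <- y + b$data
  ag_node(y, backward = function(n) {
    dv <- matrix(0, C, ncol(v))
    dw <- numeric(k)
    for (j in seq_len(k)) {
      dv <- dv + w$data[j] * shift_rows(n$grad, (j - 1L) - pad)
      dw[j] <- sum(shift_rows(v, pad - (j - 1L)) * n$grad)
    }
    acc_grad(x, dv)
    acc_grad(w, dw)
    if (!is.null(b)) acc_grad(b, sum(n$grad))
  })
}

ag_dropout <- function(x, p, training = FALSE) {
  if (!training || p <= 0) return(x)
  mask <- (array(runif(length(x$data)), dim = dim_of(x$data)) >= p) / (1 - p)
  ag_node(x$data * mask, backward = function(n) acc_grad(x, n$grad * mask))
}

## Softmax cross-entropy over logits (K,N) with integer labels in 1..K.
## Returns a scalar node; $probs holds the softmax for reuse.
ag_softmax_xent <- function(logits, labels) {
  z <- logits$data
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  N <- ncol(z)
  sel <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  n <- ag_node(loss, backward = function(n) {
    d <- p
    d[sel] <- d[sel] - 1
    acc_grad(logits, d / N * n$grad)
  })
  n$probs <- p
  n
}

ag_reshape <- function(x, dims) {
  d0 <- dim_of(x$data)
  y <- x$data
  dim(y) <- dims
  ag_node(y, backward = function(n) {
    g <- n$grad
    dim(g) <- d0
    acc_grad(x, g)
  })
}

## Sum of the target-class logit over the batch (Grad-CAM objective).
ag_logit_sum <- function(logits, class_idx) {
  ag_node(sum(logits$data[class_idx, ]), backward = function(n) {
    g <- matrix(0, nrow(logits$data), ncol(logits$data))
    g[class_idx, ] <- n$grad
    acc_grad(logits, g)
  })
}
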