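## Attention blocks. The centerpiece is FSCA (fused spatial-channel
## attention): a directional coordinate-gating stage (average pooling along
## the X and Y axes, a shared normalizing 1x1 convolution on the
## 1x(H+W)xC concatenation, per-direction expansion, sigmoid gates) followed
## by a per-location cross-channel stage (channel max + mean stacked to two
## planes, fused by a single-output-channel convolution, sigmoid gate).
## SE, ECA, CBAM and CA are included as ablation baselines.

#' Attention block configuration
#'
#' @param reduction_ratio positive integer; channel bottleneck divisor used
#'   inside the directional (coordinate) stage and inside SE.
#' @param spatial_kernel odd positive integer; kernel size of the
#'   single-output-channel fusing convolution in the cross-channel stage.
#' @param min_reduced_channels positive integer floor on the reduced width,
#'   so narrow layers keep a usable bottleneck.
#' @param act activation between the reduce and expand convolutions of the
#'   directional stage ("hswish", "relu" or "identity").
#' @param order whether the directional stage runs before or after the
#'   cross-channel stage in the fused block.
#' @return an object of class `attention_config`.
#' @export
attention_config <- function(reduction_ratio = 32L, spatial_kernel = 7L,
                             min_reduced_channels = 8L, act = "hswish",
                             order = c("spatial_first", "channel_first")) {
  stopifnot(reduction_ratio >= 1L, min_reduced_channels >= 1L,
            spatial_kernel >= 1L)
  if (spatial_kernel %% 2L == 0L) stop("spatial_kernel must be odd")
  structure(list(
    reduction_ratio = as.integer(reduction_ratio),
    spatial_kernel = as.integer(spatial_kernel),
    min_reduced_channels = as.integer(min_reduced_channels),
    act = act,
    order = match.arg(order)
  ), class = "attention_config")
}

reduced_width <- function(C, cfg) {
  max(C %/% cfg$reduction_ratio, min(cfg$min_reduced_channels, C))
}

## Round v to the nearest multiple of `divisor`, never dropping below 90%.
make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, (as.integer(v) + divisor %/% 2L) %/% divisor * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

## Replace a gate node with exact ones when the module is switched to its
## identity configuration (used by the gate-identity invariants).
maybe_force <- function(m, gate) {
  if (isTRUE(m$force_gates)) ag_input(array(1, dim = dim(gate$data))) else gate
}

#' @keywords internal
force_gates <- function(m, on = TRUE) {
  m$force_gates <- on
  if (!is.null(m$children)) for (ch in m$children) force_gates(ch, on)
  invisible(m)
}

## --- directional (X/Y coordinate) stage -----------------------------------

mod_fsca_spatial <- function(C, cfg = attention_config(), prefix = "fsca_sp") {
  Cr <- reduced_width(C, cfg)
  reduce <- mod_conv2d(C, Cr, 1L, bias = FALSE, prefix = paste0(prefix, ".reduce"))
  norm <- mod_bn(Cr, prefix = paste0(prefix, ".bn"))
  act <- activation_fn(cfg$act)
  exp_h <- mod_conv2d(Cr, C, 1L, bias = TRUE, prefix = paste0(prefix, ".expand_h"))
  exp_w <- mod_conv2d(Cr, C, 1L, bias = TRUE, prefix = paste0(prefix, ".expand_w"))
  m <- new_module(prefix)
  m$params <- c(reduce$params, norm$params, exp_h$params, exp_w$params)
  m$states <- norm$states
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$data)
    H <- d[1]; W <- d[2]
    ph <- ag_permute(ag_mean_w(x), c(2L, 1L, 3L, 4L)) # (1,H,C,N)
    pw <- ag_mean_h(x)                                # (1,W,C,N)
    z <- ag_concat(list(ph, pw), axis = 2L)           # (1,H+W,C,N)
    z <- act(norm$forward(reduce$forward(z, training), training))
    zh <- ag_slice(z, 2L, 1L, H)
    zw <- ag_slice(z, 2L, H + 1L, H + W)
    gh <- ag_sigmoid(exp_h$forward(zh, training))     # (1,H,C,N)
    gw <- ag_sigmoid(exp_w$forward(zw, training))     # (1,W,C,N)
    gh <- ag_permute(gh, c(2L, 1L, 3L, 4L))           # (H,1,C,N)
    gh <- maybe_force(m, gh)
    gw <- maybe_force(m, gw)
    ag_mul(ag_mul(x, gh), gw)
  }
  m$macs_fn <- function(h, w) {
    list(h = h, w = w,
         macs = (h + w) * Cr * C + h * C * Cr + w * C * Cr)
  }
  m
}

## --- per-location cross-channel stage -------------------------------------

mod_fsca_channel <- function(C, cfg = attention_config(), prefix = "fsca_ch") {
  k <- cfg$spatial_kernel
  fuse <- mod_conv2d(2L, 1L, k, bias = TRUE, prefix = paste0(prefix, ".fuse"))
  m <- new_module(prefix)
  m$params <- fuse$params
  m$forward <- function(x, training = FALSE) {
    mx <- ag_chan_max(x)                              # (H,W,1,N)
    mn <- ag_chan_mean(x)
    s <- ag_concat(list(mx, mn), axis = 3L)           # (H,W,2,N)
    g <- ag_sigmoid(fuse$forward(s, training))        # (H,W,1,N)
    g <- maybe_force(m, g)
    ag_mul(x, g)
  }
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = h * w * (k * k * 2))
  m
}

## --- fused block ----------------------------------------------------------

mod_fsca <- function(C, cfg = attention_config(), prefix = "fsca") {
  sp <- mod_fsca_spatial(C, cfg, paste0(prefix, ".spatial"))
  chn <- mod_fsca_channel(C, cfg, paste0(prefix, ".channel"))
  order <- if (identical(cfg$order, "channel_first")) list(chn, sp) else list(sp, chn)
  m <- mod_seq(order, prefix = prefix)
  m
}

## --- squeeze-and-excitation -----------------------------------------------

mod_se <- function(C, cfg = attention_config(reduction_ratio = 4L), prefix = "se") {
  sq <- make_divisible(C %/% cfg$reduction_ratio, 8L)
  fc1 <- mod_dense(C, sq, bias = TRUE, prefix = paste0(prefix, ".fc1"))
  fc2 <- mod_dense(sq, C, bias = TRUE, prefix = paste0(prefix, ".fc2"))
  m <- new_module(prefix)
  m$params <- c(fc1$params, fc2$params)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$data)
    v <- ag_gap(x)
    v <- ag_relu(fc1$forward(v, training))
    v <- ag_hsigmoid(fc2$forward(v, training))
    g <- ag_reshape(v, c(1L, 1L, d[3], d[4]))
    g <- maybe_force(m, g)
    ag_mul(x, g)
  }
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = C * sq + sq * C)
  m
}

## --- efficient channel attention ------------------------------------------

eca_kernel_size <- function(C, gamma = 2, b = 1) {
  t <- as.integer(abs((log2(C) + b) / gamma))
  k <- if (t %% 2L == 1L) t else t + 1L
  max(k, 3L)
}

mod_eca <- function(C, cfg = attention_config(), prefix = "eca") {
  k <- eca_kernel_size(C)
  m <- new_module(prefix)
  m$params[[paste0(prefix, ".w")]] <- ag_param(rnorm(k, sd = sqrt(2 / k)))
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$data)
    v <- ag_gap(x)
    v <- ag_sigmoid(ag_conv1d_channels(v, m$params[[paste0(prefix, ".w")]]))
    g <- ag_reshape(v, c(1L, 1L, d[3], d[4]))
    g <- maybe_force(m, g)
    ag_mul(x, g)
  }
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = C * k)
  m
}

## --- convolutional block attention (CBAM) ---------------------------------

mod_cbam <- function(C, cfg = attention_config(spatial_kernel = 7L), prefix = "cbam") {
  red <- max(C %/% 16L, 1L)
  fc1 <- mod_dense(C, red, bias = TRUE, prefix = paste0(prefix, ".fc1"))
  fc2 <- mod_dense(red, C, bias = TRUE, prefix = paste0(prefix, ".fc2"))
  k <- cfg$spatial_kernel
  fuse <- mod_conv2d(2L, 1L, k, bias = TRUE, prefix = paste0(prefix, ".fuse"))
  m <- new_module(prefix)
  m$params <- c(fc1$params, fc2$params, fuse$params)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$data)
    mlp <- function(v) fc2$forward(ag_relu(fc1$forward(v, training)), training)
    gc <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
    gc <- ag_reshape(gc, c(1L, 1L, d[3], d[4]))
    gc <- maybe_force(m, gc)
    x <- ag_mul(x, gc)
    s <- ag_concat(list(ag_chan_max(x), ag_chan_mean(x)), axis = 3L)
    gs <- ag_sigmoid(fuse$forward(s, training))
    gs <- maybe_force(m, gs)
    ag_mul(x, gs)
  }
  m$macs_fn <- function(h, w) {
    list(h = h, w = w, macs = 2 * (C * red + red * C) + h * w * (k * k * 2))
  }
  m
}

## --- registry -------------------------------------------------------------

#' Construct an attention block by name
#'
#' Builds one of the registered gating blocks, all of which preserve the
#' (H, W, C, N) shape of their input and multiply it by sigmoid weights in
#' (0, 1). `"fsca"` is the fused spatial-channel block; `"ca"` is the
#' directional (coordinate) stage alone; `"se"`, `"eca"` and `"cbam"` are
#' the published baselines; `"none"` is the identity.
#'
#' @param name one of `"none"`, `"se"`, `"eca"`, `"cbam"`, `"ca"`, `"fsca"`.
#' @param channels number of input channels the block will see.
#' @param cfg an [attention_config()].
#' @param prefix parameter name prefix.
#' @return a network module; apply it with [apply_module()].
#' @export
#' @examples
#' blk <- attention_block("fsca", channels = 8)
#' x <- array(rnorm(6 * 5 * 8), dim = c(6, 5, 8, 1))
#' y <- apply_module(blk, x)
#' dim(y)
attention_block <- function(name, channels, cfg = NULL, prefix = name) {
  if (!name %in% names(attention_registry())) {
    stop("unknown attention block '", name, "'; registered: ",
         paste(names(attention_registry()), collapse = ", "))
  }
  ctor <- attention_registry()[[name]]
  ctor(channels, cfg, prefix)
}

attention_registry <- function() {
  list(
    none = function(C, cfg, prefix) mod_identity(),
    se = function(C, cfg, prefix) {
      mod_se(C, cfg %||% attention_config(reduction_ratio = 4L), prefix)
    },
    eca = function(C, cfg, prefix) mod_eca(C, cfg %||% attention_config(), prefix),
    cbam = function(C, cfg, prefix) mod_cbam(C, cfg %||% attention_config(), prefix),
    ca = function(C, cfg, prefix) mod_fsca_spatial(C, cfg %||% attention_config(), prefix),
    fsca = function(C, cfg, prefix) mod_fsca(C, cfg %||% attention_config(), prefix)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a module to a plain array
#'
#' Convenience wrapper running a module's forward pass outside any training
#' tape. A 3-d (H, W, C) input is treated as a single-image batch and
#' returned in 3-d; a 4-d (H, W, C, N) input is returned in 4-d.
#'
#' @param m a module, e.g. from [attention_block()].
#' @param x numeric array, 3-d or 4-d, finite values.
#' @param training logical; use batch statistics in any normalization layers.
#' @return array of the same shape as `x` (attention blocks and other
#'   shape-preserving modules) or whatever shape the module produces.
#' @export
apply_module <- function(m, x, training = FALSE) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("input must be a finite numeric array")
  nd <- length(dim(x) %||% numeric(0))
  if (nd == 3L) {
    dim(x) <- c(dim(x), 1L)
  } else if (nd != 4L) {
    stop("input must be a 3-d (H,W,C) or 4-d (H,W,C,N) array, got ", nd, " dims")
  }
  out <- m$forward(ag_input(x), training = training)$data
  if (nd == 3L && length(dim(out)) == 4L && dim(out)[4] == 1L) {
    dim(out) <- dim(out)[1:3]
  }
  out
}
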