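## Multi-scale feature-extraction front end: four parallel convolutions of
## kernel size 1, 3, 5 and 7 over the input image, concatenated along the
## channel axis and fused by a 1x1 convolution, placed ahead of the
## backbone stem so the network sees several receptive fields at once.

#' Multi-scale front-end configuration
#'
#' @param kernel_sizes ordered vector of odd kernel sizes, one per parallel
#'   branch; default `c(1, 3, 5, 7)`.
#' @param branch_channels output channels of each branch.
#' @param fuse_channels output channels of the 1x1 fusing convolution handed
#'   to the backbone stem; ignored when `fuse = "concat"`.
#' @param in_channels input image channels.
#' @param fuse `"conv"` (concatenation + 1x1 fuse, the default) or
#'   `"concat"` (concatenation only, for ablation).
#' @param act per-branch activation after normalization.
#' @return an object of class `multiscale_config`.
#' @export
multiscale_config <- function(kernel_sizes = c(1L, 3L, 5L, 7L),
                              branch_channels = 8L, fuse_channels = 16L,
                              in_channels = 3L,
                              fuse = c("conv", "concat"), act = "hswish") {
  if (any(kernel_sizes %% 2L == 0L)) stop("all kernel sizes must be odd")
  stopifnot(branch_channels >= 1L, fuse_channels >= 1L, in_channels >= 1L)
  fuse <- match.arg(fuse)
  structure(list(
    kernel_sizes = as.integer(kernel_sizes),
    branch_channels = as.integer(branch_channels),
    fuse_channels = as.integer(fuse_channels),
    in_channels = as.integer(in_channels),
    fuse = fuse,
    act = act
  ), class = "multiscale_config")
}

#' @keywords internal
multiscale_out_channels <- function(cfg) {
  if (identical(cfg$fuse, "concat")) {
    length(cfg$kernel_sizes) * cfg$branch_channels
  } else {
    cfg$fuse_channels
  }
}

mod_multiscale <- function(cfg = multiscale_config(), prefix = "frontend") {
  branches <- lapply(seq_along(cfg$kernel_sizes), function(i) {
    mod_conv_bn_act(cfg$in_channels, cfg$branch_channels, cfg$kernel_sizes[i],
                    stride = 1L, act = cfg$act,
                    prefix = sprintf("%s.branch%d", prefix, i))
  })
  concat_ch <- length(cfg$kernel_sizes) * cfg$branch_channels
  fuse <- if (identical(cfg$fuse, "conv")) {
    mod_conv2d(concat_ch, cfg$fuse_channels, 1L, bias = FALSE,
               prefix = paste0(prefix, ".fuse"))
  } else {
    NULL
  }
  m <- new_module(prefix)
  m$children <- c(branches, if (!is.null(fuse)) list(fuse))
  for (ch in m$children) {
    m$params <- c(m$params, ch$params)
    m$states <- c(m$states, ch$states)
  }
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$data)
    if (d[3] != cfg$in_channels) {
      stop("front end expects ", cfg$in_channels, " input channels, got ", d[3])
    }
    outs <- lapply(branches, function(b) b$forward(x, training))
    y <- ag_concat(outs, axis = 3L)
    if (!is.null(fuse)) y <- fuse$forward(y, training)
    y
  }
  m$macs_fn <- function(h, w) {
    total <- sum(vapply(branches, function(b) b$macs_fn(h, w)$macs, numeric(1)))
    if (!is.null(fuse)) total <- total + fuse$macs_fn(h, w)$macs
    list(h = h, w = w, macs = total)
  }
  m
}
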