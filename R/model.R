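## Declarative model assembly: inverted-residual bottlenecks, the
## MobileNet v3-Large baseline, and the MFS variant in which a multi-scale
## front end precedes the stem and FSCA replaces every SE site. Parameter
## and multiply-accumulate accounting is analytic and deterministic.

#' Inverted-residual bottleneck specification
#'
#' @param in_channels,expand_channels,out_channels channel widths; the 1x1
#'   expansion convolution is omitted when `expand_channels == in_channels`.
#' @param kernel odd depthwise kernel size.
#' @param stride 1 or 2. The residual connection is present iff
#'   `stride == 1` and `in_channels == out_channels`.
#' @param activation `"relu"` or `"hswish"`.
#' @param attention registered attention block name (`"none"`, `"se"`,
#'   `"fsca"`, ...), inserted on the expanded representation after the
#'   depthwise convolution.
#' @return an object of class `bottleneck_spec`.
#' @export
bottleneck_spec <- function(in_channels, expand_channels, out_channels,
                            kernel = 3L, stride = 1L, activation = "relu",
                            attention = "none") {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2, got ", stride)
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  stopifnot(in_channels >= 1L, expand_channels >= 1L, out_channels >= 1L)
  structure(list(
    in_channels = as.integer(in_channels),
    expand_channels = as.integer(expand_channels),
    out_channels = as.integer(out_channels),
    kernel = as.integer(kernel),
    stride = as.integer(stride),
    activation = activation,
    attention = attention
  ), class = "bottleneck_spec")
}

#' Build a single inverted-residual bottleneck block
#'
#' Expansion (1x1, when widening) -> depthwise (k x k, stride s) ->
#' attention block on the expanded representation -> linear 1x1 projection,
#' with a residual connection when stride is 1 and the widths match.
#'
#' @param spec a [bottleneck_spec()].
#' @param attention_cfg an [attention_config()] for the block's attention.
#' @param prefix parameter name prefix.
#' @return a network module.
#' @export
build_bottleneck <- function(spec, attention_cfg = NULL, prefix = "bneck") {
  stopifnot(inherits(spec, "bottleneck_spec"))
  use_res <- spec$stride == 1L && spec$in_channels == spec$out_channels
  expand <- if (spec$expand_channels != spec$in_channels) {
    mod_conv_bn_act(spec$in_channels, spec$expand_channels, 1L,
                    act = spec$activation, prefix = paste0(prefix, ".expand"))
  } else {
    NULL
  }
  dw <- mod_conv_bn_act(spec$expand_channels, spec$expand_channels,
                        spec$kernel, stride = spec$stride,
                        groups = spec$expand_channels, act = spec$activation,
                        prefix = paste0(prefix, ".dw"))
  att <- attention_block(spec$attention, spec$expand_channels, attention_cfg,
                         prefix = paste0(prefix, ".att"))
  project <- mod_seq(list(
    mod_conv2d(spec$expand_channels, spec$out_channels, 1L, bias = FALSE,
               prefix = paste0(prefix, ".project.conv")),
    mod_bn(spec$out_channels, prefix = paste0(prefix, ".project.bn"))
  ))
  inner <- c(if (!is.null(expand)) list(expand), list(dw, att, project))
  m <- new_module(prefix)
  m$children <- inner
  for (ch in inner) {
    m$params <- c(m$params, ch$params)
    m$states <- c(m$states, ch$states)
  }
  m$spec <- spec
  m$forward <- function(x, training = FALSE) {
    h <- x
    for (ch in inner) h <- ch$forward(h, training)
    if (use_res) h <- ag_add(h, x) else h
  }
  m$macs_fn <- function(h, w) {
    total <- 0
    for (ch in inner) {
      g <- ch$macs_fn(h, w)
      h <- g$h; w <- g$w; total <- total + g$macs
    }
    list(h = h, w = w, macs = total)
  }
  m
}

## The published MobileNet v3-Large bottleneck table:
## in, kernel, expand, out, attention site, activation, stride.
v3_large_rows <- function(attention = "se") {
  a <- attention
  rows <- list(
    list(16L, 3L, 16L, 16L, "none", "relu", 1L),
    list(16L, 3L, 64L, 24L, "none", "relu", 2L),
    list(24L, 3L, 72L, 24L, "none", "relu", 1L),
    list(24L, 5L, 72L, 40L, a, "relu", 2L),
    list(40L, 5L, 120L, 40L, a, "relu", 1L),
    list(40L, 5L, 120L, 40L, a, "relu", 1L),
    list(40L, 3L, 240L, 80L, "none", "hswish", 2L),
    list(80L, 3L, 200L, 80L, "none", "hswish", 1L),
    list(80L, 3L, 184L, 80L, "none", "hswish", 1L),
    list(80L, 3L, 184L, 80L, "none", "hswish", 1L),
    list(80L, 3L, 480L, 112L, a, "hswish", 1L),
    list(112L, 3L, 672L, 112L, a, "hswish", 1L),
    list(112L, 5L, 672L, 160L, a, "hswish", 2L),
    list(160L, 5L, 960L, 160L, a, "hswish", 1L),
    list(160L, 5L, 960L, 160L, a, "hswish", 1L)
  )
  lapply(rows, function(r) {
    bottleneck_spec(r[[1]], r[[3]], r[[4]], kernel = r[[2]], stride = r[[7]],
                    activation = r[[6]], attention = r[[5]])
  })
}

#' Full model specification
#'
#' @param bottlenecks ordered list of [bottleneck_spec()] objects; each
#'   `in_channels` must equal its predecessor's `out_channels`.
#' @param num_classes number of output classes (>= 2).
#' @param frontend a [multiscale_config()] or `NULL` for no front end.
#' @param stem list with `out_channels`, `kernel`, `stride`, `act`.
#' @param head list with `conv_channels` (1x1 conv after the last
#'   bottleneck), `hidden` (classifier hidden width, 0 to skip) and
#'   `dropout`.
#' @param attention_cfg shared [attention_config()] for all attention sites.
#' @param input_size nominal square input resolution (used by reporting).
#' @param name model name for reports.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(bottlenecks, num_classes, frontend = NULL,
                       stem = list(out_channels = 16L, kernel = 3L,
                                   stride = 2L, act = "hswish"),
                       head = list(conv_channels = 960L, hidden = 1280L,
                                   dropout = 0.2),
                       attention_cfg = NULL, input_size = 224L,
                       name = "model") {
  if (num_classes < 2L) stop("num_classes must be >= 2")
  stem_in <- if (is.null(frontend)) 3L else multiscale_out_channels(frontend)
  prev <- stem$out_channels
  for (i in seq_along(bottlenecks)) {
    b <- bottlenecks[[i]]
    if (b$in_channels != prev) {
      stop(sprintf("bottleneck %d expects %d input channels but receives %d",
                   i, b$in_channels, prev))
    }
    prev <- b$out_channels
  }
  structure(list(
    frontend = frontend, stem = c(stem, list(in_channels = stem_in)),
    bottlenecks = bottlenecks, head = head,
    num_classes = as.integer(num_classes),
    attention_cfg = attention_cfg,
    input_size = as.integer(input_size), name = name
  ), class = "model_spec")
}

#' MobileNet v3-Large specification
#' @param num_classes number of output classes.
#' @return a [model_spec()] for the standard v3-Large layout: 3x3 stride-2
#'   stem of 16 channels, 15 bottlenecks with SE on the published subset,
#'   960-channel final convolution and a 1280-wide classifier.
#' @export
spec_mobilenet_v3_large <- function(num_classes) {
  model_spec(v3_large_rows("se"), num_classes,
             attention_cfg = attention_config(reduction_ratio = 4L),
             name = "mobilenet_v3_large")
}

#' MobileNet-MFS specification
#'
#' The v3-Large layout with (a) the multi-scale front end ahead of the stem
#' and (b) FSCA in place of every SE site; all other layers are identical,
#' so disabling the front end and mapping the attention back to SE recovers
#' the baseline exactly.
#'
#' @param num_classes number of output classes.
#' @param frontend a [multiscale_config()], or `NULL` to disable.
#' @param attention attention block name placed at the SE sites.
#' @param attention_cfg an [attention_config()]; defaults follow the
#'   coordinate-attention convention (reduction 32, floor 8) with a 7x7
#'   fusing kernel.
#' @return a [model_spec()].
#' @export
spec_mobilenet_mfs <- function(num_classes, frontend = multiscale_config(),
                               attention = "fsca", attention_cfg = NULL) {
  if (is.null(attention_cfg)) {
    attention_cfg <- if (identical(attention, "se")) {
      attention_config(reduction_ratio = 4L)
    } else {
      attention_config()
    }
  }
  stem_in <- if (is.null(frontend)) 3L else multiscale_out_channels(frontend)
  model_spec(v3_large_rows(attention), num_classes, frontend = frontend,
             stem = list(out_channels = 16L, kernel = 3L, stride = 2L,
                         act = "hswish"),
             attention_cfg = attention_cfg,
             name = if (is.null(frontend) && identical(attention, "se"))
               "mobilenet_v3_large" else "mobilenet_mfs")
}

#' Compact MFS specification for desk-scale experiments
#'
#' A narrow, shallow member of the same architecture family (multi-scale
#' front end, inverted-residual bottlenecks with FSCA at every site) sized
#' so a full training run on a synthetic benchmark finishes in minutes on
#' one CPU core.
#'
#' @param num_classes number of output classes.
#' @param input_size nominal input resolution.
#' @return a [model_spec()].
#' @export
spec_mfs_compact <- function(num_classes, input_size = 96L) {
  fe <- multiscale_config(branch_channels = 1L, fuse_channels = 8L)
  bn <- list(
    bottleneck_spec(8L, 16L, 12L, kernel = 3L, stride = 2L,
                    activation = "hswish", attention = "fsca"),
    bottleneck_spec(12L, 24L, 12L, kernel = 3L, stride = 1L,
                    activation = "hswish", attention = "fsca"),
    bottleneck_spec(12L, 36L, 16L, kernel = 5L, stride = 2L,
                    activation = "hswish", attention = "fsca"),
    bottleneck_spec(16L, 48L, 16L, kernel = 5L, stride = 1L,
                    activation = "hswish", attention = "fsca")
  )
  model_spec(bn, num_classes, frontend = fe,
             stem = list(out_channels = 8L, kernel = 3L, stride = 2L,
                         act = "hswish"),
             head = list(conv_channels = 64L, hidden = 64L, dropout = 0),
             attention_cfg = attention_config(reduction_ratio = 8L,
                                              min_reduced_channels = 4L),
             input_size = input_size, name = "mfs_compact")
}

#' Build a network from a model specification
#'
#' @param spec a [model_spec()].
#' @return a model object (environment) with `$forward`, `$params`,
#'   `$states`, `$spec` and an ordered `$stages` list whose names are the
#'   layer names accepted by [gradcam()].
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  stages <- list()
  if (!is.null(spec$frontend)) {
    stages$frontend <- mod_multiscale(spec$frontend, prefix = "frontend")
  }
  stages$stem <- mod_conv_bn_act(spec$stem$in_channels, spec$stem$out_channels,
                                 spec$stem$kernel, stride = spec$stem$stride,
                                 act = spec$stem$act, prefix = "stem")
  for (i in seq_along(spec$bottlenecks)) {
    nm <- sprintf("bneck%02d", i)
    stages[[nm]] <- build_bottleneck(spec$bottlenecks[[i]], spec$attention_cfg,
                                     prefix = nm)
  }
  last_c <- spec$bottlenecks[[length(spec$bottlenecks)]]$out_channels
  stages$head_conv <- mod_conv_bn_act(last_c, spec$head$conv_channels, 1L,
                                      act = "hswish", prefix = "head.conv")
  cls <- list()
  if (spec$head$hidden > 0L) {
    cls$hidden <- mod_dense(spec$head$conv_channels, spec$head$hidden,
                            prefix = "head.hidden")
    cls$out <- mod_dense(spec$head$hidden, spec$num_classes,
                         prefix = "head.classifier")
  } else {
    cls$out <- mod_dense(spec$head$conv_channels, spec$num_classes,
                         prefix = "head.classifier")
  }

  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$stages <- stages
  model$classifier <- cls
  model$params <- list()
  model$states <- list()
  for (s in stages) {
    model$params <- c(model$params, s$params)
    model$states <- c(model$states, s$states)
  }
  for (s in cls) model$params <- c(model$params, s$params)
  if (anyDuplicated(names(model$params))) stop("duplicate parameter names")

  model$forward <- function(x, training = FALSE, capture = FALSE) {
    feats <- if (capture) list() else NULL
    h <- x
    for (nm in names(stages)) {
      h <- stages[[nm]]$forward(h, training)
      if (capture) feats[[nm]] <- h
    }
    v <- ag_gap(h)
    if (!is.null(cls$hidden)) {
      v <- ag_hswish(cls$hidden$forward(v, training))
      v <- ag_dropout(v, spec$head$dropout, training)
    }
    logits <- cls$out$forward(v, training)
    if (capture) list(logits = logits, feats = feats) else logits
  }
  class(model) <- "lfm_model"
  model
}

#' @export
print.lfm_model <- function(x, ...) {
  cat(sprintf("<%s> %d classes, %s parameters\n", x$spec$name,
              x$spec$num_classes, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Build the MobileNet v3-Large baseline
#' @param num_classes number of output classes.
#' @return a model object.
#' @export
build_mobilenet_v3_large <- function(num_classes) {
  build_model(spec_mobilenet_v3_large(num_classes))
}

#' Build MobileNet-MFS
#' @inheritParams spec_mobilenet_mfs
#' @return a model object.
#' @export
build_mobilenet_mfs <- function(num_classes, frontend = multiscale_config(),
                                attention = "fsca", attention_cfg = NULL) {
  build_model(spec_mobilenet_mfs(num_classes, frontend, attention,
                                 attention_cfg))
}

#' Count trainable parameters
#' @param model a model object from [build_model()].
#' @return integer count of trainable scalars; independent of input size.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$data), numeric(1)))
}

#' Count multiply-accumulate operations at a fixed input size
#'
#' Convention: one MAC per multiply-add inside convolutions
#' (`out_H * out_W * out_C * in_C * k * k / groups`) and fully connected
#' layers; normalization, activation and elementwise gating ops are
#' excluded.
#'
#' @param model a model object.
#' @param input_hw integer vector `c(H, W)`; defaults to the spec's
#'   nominal input size.
#' @return numeric MAC count.
#' @export
count_macs <- function(model, input_hw = NULL) {
  if (is.null(input_hw)) input_hw <- rep(model$spec$input_size, 2L)
  h <- input_hw[1]; w <- input_hw[2]
  total <- 0
  for (s in model$stages) {
    g <- s$macs_fn(h, w)
    h <- g$h; w <- g$w; total <- total + g$macs
  }
  for (s in model$classifier) total <- total + s$macs_fn(1, 1)$macs
  total
}

#' Per-stage parameter and MAC table
#' @param model a model object.
#' @param input_hw integer vector `c(H, W)`.
#' @return data.frame with one row per stage: name, output spatial size,
#'   parameter count and MAC count.
#' @export
model_layer_table <- function(model, input_hw = NULL) {
  if (is.null(input_hw)) input_hw <- rep(model$spec$input_size, 2L)
  h <- input_hw[1]; w <- input_hw[2]
  rows <- list()
  for (nm in names(model$stages)) {
    s <- model$stages[[nm]]
    g <- s$macs_fn(h, w)
    rows[[length(rows) + 1L]] <- data.frame(
      stage = nm, out_h = g$h, out_w = g$w,
      params = module_param_count(s), macs = g$macs)
    h <- g$h; w <- g$w
  }
  for (nm in names(model$classifier)) {
    s <- model$classifier[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      stage = paste0("classifier.", nm), out_h = 1L, out_w = 1L,
      params = module_param_count(s), macs = s$macs_fn(1, 1)$macs)
  }
  do.call(rbind, rows)
}

#' Forward pass returning class scores
#'
#' @param model a model object.
#' @param images array (H, W, C, N) or a single (H, W, C) image.
#' @param batch_size mini-batch size for the sweep.
#' @return list with `logits` and softmax `probs`, both (num_classes, N)
#'   matrices.
#' @export
predict_scores <- function(model, images, batch_size = 32L) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  N <- dim(images)[4]
  K <- model$spec$num_classes
  logits <- matrix(0, K, N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    xb <- images[, , , idx, drop = FALSE]
    logits[, idx] <- model$forward(ag_input(xb), training = FALSE)$data
  }
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  probs <- sweep(ez, 2, colSums(ez), "/")
  list(logits = logits, probs = probs)
}
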