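## Network module constructors. A module is an environment with
##   $forward(x, training)  taking and returning autodiff nodes,
##   $params                a named list of ag_param objects,
##   $states                a named list of batch-norm running-moment envs,
##   $macs_fn(h, w)         multiply-accumulate accounting at a spatial size.
## Names are dot-separated paths ("stem.conv.w"), which is what the
## transfer-learning loader matches on.

new_module <- function(prefix) {
  m <- new.env(parent = emptyenv())
  m$prefix <- prefix
  m$params <- list()
  m$states <- list()
  class(m) <- "lfm_module"
  m
}

same_pad <- function(k) (k - 1L) %/% 2L

conv_out_hw <- function(h, w, k, stride, pad) {
  c(
    (h + 2L * pad - k) %/% stride + 1L,
    (w + 2L * pad - k) %/% stride + 1L
  )
}

## He-normal initialization for a conv weight (k,k,Cg,Cout).
init_conv_w <- function(k, cg, cout) {
  sd <- sqrt(2 / (k * k * cg))
  array(rnorm(k * k * cg * cout, sd = sd), dim = c(k, k, cg, cout))
}

mod_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, groups = 1L,
                       bias = FALSE, prefix = "conv") {
  if (k %% 2L == 0L) stop("conv kernel must be odd, got ", k)
  if (in_ch %% groups != 0L) stop("in_channels not divisible by groups")
  if (is.null(pad)) pad <- same_pad(k)
  m <- new_module(prefix)
  cg <- in_ch %/% groups
  m$params[[paste0(prefix, ".w")]] <- ag_param(init_conv_w(k, cg, out_ch))
  if (bias) m$params[[paste0(prefix, ".b")]] <- ag_param(numeric(out_ch))
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params[[paste0(prefix, ".w")]],
              if (bias) m$params[[paste0(prefix, ".b")]] else NULL,
              stride = stride, pad = pad, groups = groups)
  }
  m$macs_fn <- function(h, w) {
    o <- conv_out_hw(h, w, k, stride, pad)
    list(h = o[1], w = o[2],
         macs = as.numeric(o[1]) * o[2] * out_ch * (k * k * cg))
  }
  m
}

mod_bn <- function(C, prefix = "bn", momentum = 0.1, eps = 1e-5) {
  m <- new_module(prefix)
  m$params[[paste0(prefix, ".gamma")]] <- ag_param(rep(1, C))
  m$params[[paste0(prefix, ".beta")]] <- ag_param(rep(0, C))
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, C)
  st$var <- rep(1, C)
  m$states[[prefix]] <- st
  m$forward <- function(x, training = FALSE) {
    ag_bn2d(x, m$params[[paste0(prefix, ".gamma")]],
            m$params[[paste0(prefix, ".beta")]], st,
            training = training, momentum = momentum, eps = eps)
  }
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = 0)
  m
}

mod_act <- function(name) {
  m <- new_module(name)
  fn <- activation_fn(name)
  m$forward <- function(x, training = FALSE) fn(x)
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = 0)
  m
}

mod_identity <- function() {
  m <- new_module("identity")
  m$forward <- function(x, training = FALSE) x
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = 0)
  m
}

mod_dense <- function(in_ch, out_ch, bias = TRUE, prefix = "fc") {
  m <- new_module(prefix)
  sd <- sqrt(2 / (in_ch + out_ch))
  m$params[[paste0(prefix, ".w")]] <- ag_param(matrix(rnorm(out_ch * in_ch, sd = sd), out_ch, in_ch))
  if (bias) m$params[[paste0(prefix, ".b")]] <- ag_param(numeric(out_ch))
  m$forward <- function(x, training = FALSE) {
    ag_dense(x, m$params[[paste0(prefix, ".w")]],
             if (bias) m$params[[paste0(prefix, ".b")]] else NULL)
  }
  m$macs_fn <- function(h, w) list(h = h, w = w, macs = as.numeric(in_ch) * out_ch)
  m
}

## Sequential composition; child param/state names pass through unchanged.
mod_seq <- function(children, prefix = "") {
  m <- new_module(prefix)
  m$children <- children
  for (ch in children) {
    m$params <- c(m$params, ch$params)
    m$states <- c(m$states, ch$states)
  }
  m$forward <- function(x, training = FALSE) {
    for (ch in children) x <- ch$forward(x, training)
    x
  }
  m$macs_fn <- function(h, w) {
    total <- 0
    for (ch in children) {
      g <- ch$macs_fn(h, w)
      h <- g$h; w <- g$w; total <- total + g$macs
    }
    list(h = h, w = w, macs = total)
  }
  m
}

## conv + batch norm + activation, the standard building unit.
mod_conv_bn_act <- function(in_ch, out_ch, k, stride = 1L, groups = 1L,
                            act = "relu", prefix = "cba") {
  mod_seq(list(
    mod_conv2d(in_ch, out_ch, k, stride = stride, groups = groups,
               bias = FALSE, prefix = paste0(prefix, ".conv")),
    mod_bn(out_ch, prefix = paste0(prefix, ".bn")),
    mod_act(act)
  ), prefix = prefix)
}

## Count of trainable scalars in a module's parameter list.
module_param_count <- function(m) {
  sum(vapply(m$params, function(p) length(p$data), numeric(1)))
}
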