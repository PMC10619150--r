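## Grad-CAM: gradient-weighted class activation mapping. Channel weights
## are the spatial average of the target-class logit's gradient at a chosen
## convolutional stage; the map is the rectified weighted sum of that
## stage's activations, normalized by its maximum (an identically zero map
## stays zero, preserving the zero baseline) and bilinearly upsampled to
## the input size.

#' Grad-CAM heat map
#'
#' @param model a model object.
#' @param image (H, W, 3) array preprocessed as in training.
#' @param target_class integer class index (1..num_classes).
#' @param layer_name stage name from `names(model$stages)`; defaults to the
#'   last bottleneck (deepest spatial map).
#' @return object of class `heatmap`: list with `values` (H x W matrix in
#'   [0, 1]), `target_class`, `layer_name`.
#' @export
gradcam <- function(model, image, target_class, layer_name = NULL) {
  stages <- names(model$stages)
  if (is.null(layer_name)) {
    layer_name <- rev(stages[startsWith(stages, "bneck")])[1]
  }
  if (!layer_name %in% stages) {
    stop("unknown layer '", layer_name, "'; available: ",
         paste(stages, collapse = ", "))
  }
  K <- model$spec$num_classes
  if (target_class < 1L || target_class > K) {
    stop("target_class must be in 1..", K)
  }
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  ag_tape_start()
  out <- model$forward(ag_input(image), training = FALSE, capture = TRUE)
  score <- ag_logit_sum(out$logits, target_class)
  ag_backward(score)
  ag_tape_stop()
  feat <- out$feats[[layer_name]]
  A <- feat$data
  G <- feat$grad
  d <- dim(A)
  if (is.null(G)) G <- array(0, dim = d)
  w <- colMeans(matrix(G, nrow = d[1] * d[2]))          # per-channel weight
  map <- matrix(matrix(A, nrow = d[1] * d[2]) %*% w, d[1], d[2])
  map <- pmax(map, 0)
  hin <- dim(image)[1]; win <- dim(image)[2]
  if (!all(dim(map) == c(hin, win))) {
    img <- EBImage::Image(t(map))
    map <- t(EBImage::imageData(EBImage::resize(img, w = win, h = hin)))
    map <- pmax(map, 0)
  }
  ## normalize by the maximum after upsampling so the peak is exactly 1;
  ## an identically zero map stays zero
  mx <- max(map)
  if (mx > 0) map <- map / mx
  structure(list(values = map, target_class = target_class,
                 layer_name = layer_name), class = "heatmap")
}

#' Overlay a heat map on an image
#'
#' @param heatmap a [gradcam()] result (or H x W matrix in [0, 1]).
#' @param image (H, W, 3) array in [0, 1] (raw, unnormalized pixels).
#' @param alpha blend weight of the color-mapped heat map; 0 returns the
#'   image, 1 the pure color map.
#' @return (H, W, 3) array in [0, 1], valid for PNG export.
#' @export
overlay <- function(heatmap, image, alpha = 0.5) {
  values <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!all(dim(values) == dim(image)[1:2])) {
    stop("heatmap size ", paste(dim(values), collapse = "x"),
         " does not match image ", paste(dim(image)[1:2], collapse = "x"))
  }
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(values)) / 255
  cmap <- array(cols, dim = c(dim(values), 3L))
  out <- (1 - alpha) * image + alpha * cmap
  pmin(pmax(out, 0), 1)
}
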