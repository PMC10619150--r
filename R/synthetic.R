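## Procedural synthetic leaf-disease images. Each class is rendered as a
## green leaf blade (elliptical, rotated, with a main vein and side veins)
## on a soil-colored background, overlaid with class-conditional lesion
## phenotypes: many small red-orange pustules for rust, gray spots for grey
## spot, ringed tan spots for frogeye, a large chlorotic yellow region for
## brown spot, block-wise discoloration for mosaic, whitened venation for
## powdery mildew, dark olive blotches for scab. Generation is a pure
## function of (spec, seed).

#' Default class phenotype parameters
#'
#' One list entry per class, with lesion spot count / radius ranges (px at
#' 96 px image size; scaled with image size), RGB lesion color means and
#' structural flags (`ring`, `chlorosis`, `mosaic`, `vein_whiten`).
#'
#' @return named list of per-class parameter lists, in lexicographic class
#'   order.
#' @export
leaf_disease_classes <- function() {
  list(
    "Alternaria leaf spot" = list(n_spots = c(5L, 9L), radius = c(6, 9),
                                  color = c(0.48, 0.28, 0.10), ring = TRUE,
                                  ring_color = c(0.22, 0.12, 0.05)),
    "Brown spot" = list(n_spots = c(2L, 4L), radius = c(5, 8),
                        color = c(0.40, 0.25, 0.10), chlorosis = TRUE),
    "Frogeye leaf spot" = list(n_spots = c(6L, 10L), radius = c(6, 9),
                               color = c(0.70, 0.62, 0.42), ring = TRUE,
                               ring_color = c(0.50, 0.18, 0.08)),
    "Grey spot" = list(n_spots = c(8L, 14L), radius = c(5, 8),
                       color = c(0.65, 0.65, 0.68)),
    "Health" = list(n_spots = c(0L, 0L)),
    "Mosaic" = list(n_spots = c(0L, 0L), mosaic = TRUE),
    "Powdery mildew" = list(n_spots = c(3L, 6L), radius = c(4, 7),
                            color = c(0.92, 0.92, 0.90), vein_whiten = TRUE),
    "Rust" = list(n_spots = c(14L, 24L), radius = c(3, 5),
                  color = c(0.88, 0.32, 0.06)),
    "Scab" = list(n_spots = c(4L, 7L), radius = c(9, 14),
                  color = c(0.14, 0.18, 0.06))
  )
}

#' Synthetic dataset specification
#'
#' @param n_per_class images generated per class.
#' @param image_size square image side in pixels.
#' @param seed integer; generation is deterministic given the spec and seed.
#' @param classes per-class phenotype parameters, as in
#'   [leaf_disease_classes()].
#' @param noise_sd pixel Gaussian noise standard deviation.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 200L, image_size = 96L, seed = 1L,
                           classes = leaf_disease_classes(), noise_sd = 0.02) {
  stopifnot(n_per_class >= 1L, image_size >= 16L)
  structure(list(
    n_per_class = as.integer(n_per_class),
    image_size = as.integer(image_size),
    seed = as.integer(seed),
    classes = classes,
    noise_sd = noise_sd
  ), class = "synthetic_spec")
}

## Render one leaf image. Assumes the RNG is already positioned; returns
## img (S,S,3) in [0,1] and the logical lesion mask (S,S).
render_leaf_image <- function(params, S, noise_sd = 0.02) {
  yy <- matrix(seq_len(S), S, S)          # row (height) coordinate
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  cx <- S * runif(1, 0.45, 0.55)
  cy <- S * runif(1, 0.45, 0.55)
  a <- S * runif(1, 0.40, 0.48)
  b <- S * runif(1, 0.28, 0.36)
  th <- runif(1, -pi / 6, pi / 6)
  u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
  v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
  leaf <- (u / a)^2 + (v / b)^2 <= 1

  img <- array(0, dim = c(S, S, 3))
  bg <- c(0.33, 0.26, 0.18) + runif(3, -0.03, 0.03)
  base <- c(0.25, 0.45, 0.20) + runif(3, -0.04, 0.04)
  shade <- 1 - 0.25 * ((u / a)^2 + (v / b)^2)
  for (c in 1:3) {
    plane <- matrix(bg[c], S, S)
    plane[leaf] <- base[c] * shade[leaf]
    img[, , c] <- plane
  }

  ## venation: main vein along the major axis plus oblique side veins
  vein <- abs(v) < 0.8 & abs(u) < a
  n_side <- 6L
  for (k in seq_len(n_side)) {
    off <- (k - (n_side + 1) / 2) / (n_side / 2) * 0.75 * a
    slope <- sign(off + 1e-9) * runif(1, 0.5, 0.9)
    vein <- vein | (abs(v - slope * (u - off)) < 0.6 & abs(u - off) < 0.35 * a)
  }
  vein <- vein & leaf
  for (c in 1:3) {
    plane <- img[, , c]
    plane[vein] <- plane[vein] * 0.85 + 0.15 * 0.75
    img[, , c] <- plane
  }

  lesion <- matrix(FALSE, S, S)
  blend <- function(alpha, color) {
    for (c in 1:3) {
      plane <- img[, , c]
      plane <- plane * (1 - alpha) + color[c] * alpha
      img[, , c] <<- plane
    }
  }

  if (isTRUE(params$chlorosis)) {
    qx <- S * runif(1, 0.35, 0.65); qy <- S * runif(1, 0.35, 0.65)
    r <- S * runif(1, 0.25, 0.35)
    d <- sqrt((xx - qx)^2 + (yy - qy)^2)
    alpha <- pmin(pmax(1.2 - d / r, 0), 1) * 0.7
    alpha[!leaf] <- 0
    blend(alpha, c(0.78, 0.72, 0.20))
    lesion <- lesion | (alpha > 0.1)
  }

  if (isTRUE(params$mosaic)) {
    cell <- max(8L, S %/% 8L)
    for (i in seq(1L, S, by = cell)) {
      for (j in seq(1L, S, by = cell)) {
        if (runif(1) < 0.4) {
          ri <- i:min(i + cell - 1L, S)
          rj <- j:min(j + cell - 1L, S)
          sub <- matrix(FALSE, S, S)
          sub[ri, rj] <- TRUE
          sub <- sub & leaf
          col <- c(0.75, 0.74, 0.28) + runif(3, -0.05, 0.05)
          alpha <- matrix(0, S, S)
          alpha[sub] <- 0.6
          blend(alpha, col)
          lesion <- lesion | sub
        }
      }
    }
  }

  if (isTRUE(params$vein_whiten)) {
    alpha <- matrix(0, S, S)
    alpha[vein] <- 0.8
    blend(alpha, c(0.93, 0.93, 0.92))
    lesion <- lesion | vein
  }

  n_rng <- params$n_spots
  n <- if (n_rng[2] > 0L) sample(n_rng[1]:n_rng[2], 1L) else 0L
  scale <- S / 96
  if (n > 0L) {
    inside <- which(leaf)
    for (s in seq_len(n)) {
      pos <- inside[sample.int(length(inside), 1L)]
      py <- (pos - 1L) %% S + 1L
      px <- (pos - 1L) %/% S + 1L
      r <- runif(1, params$radius[1], params$radius[2]) * scale
      d <- sqrt((xx - px)^2 + (yy - py)^2)
      core <- pmin(pmax(1.5 - d / r, 0), 1) * 0.9
      core[!leaf] <- 0
      col <- params$color + runif(3, -0.04, 0.04)
      if (isTRUE(params$ring)) {
        ring_alpha <- core * (d > 0.65 * r)
        core_alpha <- core * (d <= 0.65 * r)
        blend(core_alpha, col)
        blend(ring_alpha, params$ring_color)
      } else {
        blend(core, col)
      }
      lesion <- lesion | (d <= r & leaf)
    }
  }

  img <- img + array(rnorm(length(img), sd = noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(S, S, 3)
  list(img = img, mask = lesion)
}

#' Generate synthetic images in memory
#'
#' @param spec a [synthetic_spec()].
#' @param class_names subset of class names to generate (default all).
#' @return nested list: per class, a list of `list(img, mask)` pairs.
#' @export
generate_synthetic_images <- function(spec, class_names = names(spec$classes)) {
  with_seed(spec$seed, {
    out <- list()
    for (cl in sort(names(spec$classes))) {
      imgs <- lapply(seq_len(spec$n_per_class), function(i) {
        render_leaf_image(spec$classes[[cl]], spec$image_size, spec$noise_sd)
      })
      if (cl %in% class_names) out[[cl]] <- imgs
    }
    out
  })
}

#' Generate a synthetic leaf-disease image folder
#'
#' Writes `n_per_class` PNG images per class under `dir/<class>/` and
#' returns the corresponding manifest. Byte-identical for identical
#' (spec, seed).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return a manifest data.frame over the generated files.
#' @export
generate_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  classes <- sort(names(spec$classes))
  paths <- character(0)
  labels <- character(0)
  with_seed(spec$seed, {
    for (cl in classes) {
      cl_dir <- file.path(dir, cl)
      dir.create(cl_dir, showWarnings = FALSE)
      for (i in seq_len(spec$n_per_class)) {
        r <- render_leaf_image(spec$classes[[cl]], spec$image_size,
                               spec$noise_sd)
        p <- file.path(cl_dir, sprintf("img_%04d.png", i))
        png::writePNG(r$img, p)
        paths <- c(paths, p)
        labels <- c(labels, cl)
      }
    }
  })
  new_manifest(paths, labels, classes, seed = spec$seed)
}

#' Handcrafted pixel-statistic features of an image
#'
#' Eight color/texture summaries (per-channel means and standard
#' deviations, red-green difference, mean gradient magnitude) used by the
#' nearest-class-mean reference classifier that certifies the synthetic
#' classes are separable.
#'
#' @param img (H, W, 3) array in [0, 1].
#' @return numeric vector of length 8.
#' @export
pixel_stat_features <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  gray <- (r + g + b) / 3
  gx <- abs(gray[, -1] - gray[, -ncol(gray)])
  gy <- abs(gray[-1, ] - gray[-nrow(gray), ])
  c(mean(r), mean(g), mean(b), stats::sd(r), stats::sd(g), stats::sd(b),
    mean(r - g), (mean(gx) + mean(gy)) / 2)
}
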