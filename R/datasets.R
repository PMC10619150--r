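## Dataset manifests and bookkeeping: the stratified 4:1 train/test rule,
## x3 augmentation lineage, and image-folder loading. A manifest is a
## data.frame with columns path, label, split, origin, transform, angle and
## attributes `classes` (ordered label set) and `seed`.

## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified 4:1 split counts
#'
#' Applies the per-class rule `test = floor(n / 5)`, `train = n - test`,
#' which is the deterministic reading of a 4:1 train/test ratio.
#'
#' @param per_class_counts positive integer vector of class sizes,
#'   optionally named.
#' @return data.frame with columns `n`, `train`, `test`, one row per class.
#' @export
#' @examples
#' stratified_split(c(657, 5407))
stratified_split <- function(per_class_counts) {
  if (any(per_class_counts < 1)) stop("class counts must be positive")
  n <- as.integer(per_class_counts)
  test <- n %/% 5L
  out <- data.frame(n = n, train = n - test, test = test)
  if (!is.null(names(per_class_counts))) rownames(out) <- names(per_class_counts)
  out
}

new_manifest <- function(path, label, classes, seed = NA_integer_) {
  m <- data.frame(
    path = path, label = label,
    split = NA_character_, origin = "original",
    transform = NA_character_, angle = NA_real_,
    stringsAsFactors = FALSE
  )
  attr(m, "classes") <- classes
  attr(m, "seed") <- seed
  m
}

#' Enumerate an image folder into a manifest
#'
#' Expects one subdirectory per class containing PNG/JPEG files. Classes
#' are ordered lexicographically for determinism.
#'
#' @param path directory with one subdirectory per class.
#' @return a manifest data.frame (no split assigned yet).
#' @export
load_image_folder <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", path)
  rows <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("class directory is empty: ", cl)
    data.frame(path = files, label = cl, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  new_manifest(df$path, df$label, classes)
}

#' Assign the stratified train/test split
#'
#' Randomly assigns `floor(n/5)` images of every class to the test split
#' and the rest to train, reproducibly from `seed`.
#'
#' @param manifest a manifest data.frame.
#' @param seed integer RNG seed.
#' @return the manifest with the `split` column filled in.
#' @export
assign_split <- function(manifest, seed = 1L) {
  classes <- attr(manifest, "classes")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(manifest$label == cl & manifest$origin == "original")
      if (length(idx) == 0L) stop("class has no images: ", cl)
      n_test <- length(idx) %/% 5L
      test_idx <- if (n_test > 0L) sample(idx, n_test) else integer(0)
      manifest$split[idx] <- "train"
      manifest$split[test_idx] <- "test"
    }
  })
  attr(manifest, "seed") <- as.integer(seed)
  manifest
}

#' Expand the training split by augmentation bookkeeping
#'
#' Every training original contributes `factor - 1` transformed copies,
#' recorded as manifest rows with `origin = "augmented"` and a transform
#' descriptor (horizontal flip, then rotations uniform in +/- 25 degrees).
#' Images themselves are transformed lazily at load time; the test split is
#' untouched.
#'
#' @param manifest a manifest with split assigned.
#' @param factor total multiplicity of each training original (>= 1).
#' @param seed integer RNG seed for the rotation angles.
#' @return the augmented manifest.
#' @export
augment_training_set <- function(manifest, factor = 3L, seed = 1L) {
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(manifest)
  train <- manifest[manifest$split == "train" & manifest$origin == "original", ]
  extra <- with_seed(seed, {
    copies <- lapply(seq_len(factor - 1L), function(k) {
      df <- train
      df$origin <- "augmented"
      if (k == 1L) {
        df$transform <- "flip"
        df$angle <- NA_real_
      } else {
        df$transform <- "rotate"
        df$angle <- runif(nrow(df), -25, 25)
      }
      df
    })
    do.call(rbind, copies)
  })
  out <- rbind(manifest, extra)
  attr(out, "classes") <- attr(manifest, "classes")
  attr(out, "seed") <- attr(manifest, "seed")
  rownames(out) <- NULL
  out
}

#' Write / read a manifest as CSV
#'
#' The class ordering is stored in a `# classes:` header comment.
#' @param manifest a manifest data.frame.
#' @param file path to the CSV file.
#' @return `read_manifest` returns the manifest; `write_manifest` its file
#'   path, invisibly.
#' @export
write_manifest <- function(manifest, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# classes: ",
                    paste(attr(manifest, "classes"), collapse = "|")), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  hdr <- readLines(file, n = 1L)
  classes <- strsplit(sub("^# classes: ", "", hdr), "\\|")[[1]]
  m <- utils::read.csv(file, skip = 1L, stringsAsFactors = FALSE)
  attr(m, "classes") <- classes
  m
}

## --- image decoding -------------------------------------------------------

## Read one image file to an (H, W, 3) array in [0, 1].
read_image_rgb <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    ## EBImage decodes JPEG; it stores (width, height, channel)
    aperm_img(EBImage::imageData(EBImage::readImage(path)))
  }
  if (is.null(dim(x)) || length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3] >= 4L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (dim(x)[3] == 1L) {
    x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  }
  x
}

## EBImage keeps (width, height, channel); we use (H, W, C).
aperm_img <- function(x) {
  if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
}

resize_image <- function(x, size) {
  if (all(dim(x)[1:2] == size)) return(x)
  img <- EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(img, w = size, h = size)
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

apply_augmentation <- function(x, transform, angle) {
  if (is.na(transform)) return(x)
  if (transform == "flip") return(x[, rev(seq_len(dim(x)[2])), , drop = FALSE])
  if (transform == "rotate") {
    img <- EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
    out <- EBImage::rotate(img, angle, output.dim = dim(x)[2:1], bg.col = 0)
    return(aperm(EBImage::imageData(out), c(2L, 1L, 3L)))
  }
  stop("unknown transform: ", transform)
}

#' Load the images referenced by a manifest
#'
#' Decodes, resizes, applies any recorded augmentation transforms, scales
#' to [0, 1] and normalizes by per-channel mean/sd. Unreadable files are
#' skipped with a warning and counted.
#'
#' @param manifest a manifest data.frame.
#' @param split `"train"`, `"test"` or `NULL` for all rows.
#' @param input_size square side the images are resized to.
#' @param mean,sd per-channel normalization constants (natural-image
#'   defaults).
#' @return list with `x` (H, W, 3, N array), `y` (integer labels),
#'   `labels` (character), `classes`, `skipped` (count of unreadable files).
#' @export
load_manifest_images <- function(manifest, split = NULL, input_size = 96L,
                                 mean = c(0.485, 0.456, 0.406),
                                 sd = c(0.229, 0.224, 0.225)) {
  rows <- if (is.null(split)) manifest else manifest[manifest$split %in% split, ]
  if (nrow(rows) == 0L) stop("no manifest rows selected")
  classes <- attr(manifest, "classes")
  x <- array(0, dim = c(input_size, input_size, 3L, nrow(rows)))
  keep <- logical(nrow(rows))
  skipped <- 0L
  for (i in seq_len(nrow(rows))) {
    img <- tryCatch(read_image_rgb(rows$path[i]), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", rows$path[i])
      skipped <- skipped + 1L
      next
    }
    img <- resize_image(img, input_size)
    img <- apply_augmentation(img, rows$transform[i], rows$angle[i])
    for (c in 1:3) img[, , c] <- (img[, , c] - mean[c]) / sd[c]
    x[, , , i] <- img
    keep[i] <- TRUE
  }
  x <- x[, , , keep, drop = FALSE]
  rows <- rows[keep, ]
  list(
    x = x,
    y = match(rows$label, classes),
    labels = rows$label,
    classes = classes,
    skipped = skipped
  )
}
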