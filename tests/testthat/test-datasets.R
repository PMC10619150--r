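# Dataset bookkeeping: the floor(n/5) stratified rule against the nine
# published class sizes, augmentation multiplicities, split assignment and
# manifest round-tripping.

# Published per-class totals of the nine-way apple leaf dataset.
table1_totals <- c(
  "Alternaria leaf spot" = 657, "Brown spot" = 442,
  "Frogeye leaf spot" = 3179, "Grey spot" = 356, "Health" = 879,
  "Mosaic" = 395, "Powdery mildew" = 1183, "Rust" = 2752, "Scab" = 5407
)
table1_train <- c(526, 354, 2544, 285, 704, 316, 947, 2202, 4326)
table1_test <- c(131, 88, 635, 71, 175, 79, 236, 550, 1081)

test_that("stratified 4:1 rule reproduces every published class split", {
  sp <- stratified_split(table1_totals)
  expect_equal(unname(sp$train), table1_train)
  expect_equal(unname(sp$test), table1_test)
  expect_equal(sum(sp$train), 12204)
  expect_equal(sum(sp$test), 3046)
  expect_equal(sum(sp$n), 15250)
})

test_that("floor arithmetic handles boundary class sizes", {
  sp <- stratified_split(c(5, 4, 1))
  expect_equal(sp$train, c(4, 4, 1))
  expect_equal(sp$test, c(1, 0, 0))
  expect_error(stratified_split(c(10, 0)), "positive")
})

test_that("x3 augmentation bookkeeping matches every published figure", {
  sp <- stratified_split(table1_totals)
  aug <- 3 * sp$train
  expect_equal(unname(aug),
               c(1578, 1062, 7632, 855, 2112, 948, 2841, 6606, 12978))
  expect_equal(sum(aug), 36612)
})

make_dummy_folder <- function(counts, size = 8L) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  for (cl in names(counts)) {
    d <- file.path(root, cl)
    dir.create(d)
    for (i in seq_len(counts[cl])) {
      png::writePNG(array(runif(size * size * 3), c(size, size, 3)),
                    file.path(d, sprintf("i%03d.png", i)))
    }
  }
  root
}

test_that("split assignment is a seeded, exact partition", {
  counts <- c(b_class = 11L, a_class = 7L, c_class = 5L)
  root <- make_dummy_folder(counts)
  m <- load_image_folder(root)
  expect_identical(attr(m, "classes"), c("a_class", "b_class", "c_class"))
  m1 <- assign_split(m, 42L)
  m2 <- assign_split(m, 42L)
  expect_identical(m1$split, m2$split)
  m3 <- assign_split(m, 43L)
  expect_false(identical(m1$split, m3$split))
  for (cl in attr(m, "classes")) {
    n <- sum(m1$label == cl)
    expect_equal(sum(m1$label == cl & m1$split == "test"), n %/% 5L)
    expect_equal(sum(m1$label == cl & m1$split == "train"), n - n %/% 5L)
  }
  expect_false(any(is.na(m1$split)))
})

test_that("augmentation expands only training originals", {
  root <- make_dummy_folder(c(x = 10L, y = 6L))
  m <- assign_split(load_image_folder(root), 1L)
  a <- augment_training_set(m, factor = 3L, seed = 1L)
  n_train <- sum(m$split == "train")
  expect_equal(nrow(a), nrow(m) + 2L * n_train)
  expect_equal(sum(a$origin == "augmented"), 2L * n_train)
  expect_true(all(a$split[a$origin == "augmented"] == "train"))
  expect_identical(a[a$origin == "original", c("path", "split")],
                   m[, c("path", "split")])
  for (cl in c("x", "y")) {
    expect_equal(sum(a$label == cl & a$split == "train"),
                 3L * sum(m$label == cl & m$split == "train"))
  }
  expect_identical(augment_training_set(m, factor = 1L), m)
  expect_error(augment_training_set(m, factor = 0L), "factor")
})

test_that("image folder loading handles grayscale and bad inputs", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "gray"))
  png::writePNG(matrix(runif(64), 8, 8), file.path(root, "gray", "g.png"))
  dir.create(file.path(root, "rgb"))
  png::writePNG(array(runif(192), c(8, 8, 3)), file.path(root, "rgb", "c.png"))
  m <- load_image_folder(root)
  d <- load_manifest_images(m, split = NULL, input_size = 8L)
  expect_identical(dim(d$x), c(8L, 8L, 3L, 2L))
  # grayscale replicated: identical channels after normalization is undone
  g <- d$x[, , , 1]
  expect_equal(g[, , 1] * 0.229 + 0.485, g[, , 2] * 0.224 + 0.456,
               tolerance = 1e-6)
  dir.create(file.path(root, "empty"))
  expect_error(load_image_folder(root), "empty")
})

test_that("manifests round-trip through CSV with class ordering", {
  root <- make_dummy_folder(c(p = 5L, q = 5L))
  m <- assign_split(load_image_folder(root), 9L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_identical(attr(m2, "classes"), attr(m, "classes"))
  expect_identical(m2$path, m$path)
  expect_identical(m2$split, m$split)
})
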