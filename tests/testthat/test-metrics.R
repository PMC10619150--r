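# Evaluation stack: the one-vs-rest precision/recall/F1 definitions on
# hand-checkable counts, pooled-metric identities on random confusion
# matrices, and trapezoidal AUC against the Mann-Whitney statistic.

test_that("binary toy counts give the textbook precision/recall/F1", {
  # TP = 2, FP = 1, FN = 2, TN = 6 for the positive class:
  # precision 2/3, recall 1/2, F1 = 2*(2/3 * 1/2)/(2/3 + 1/2) = 4/7
  cm <- matrix(c(2, 2, 1, 6), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r <- metrics_from_confusion(cm)
  expect_equal(r$per_class$precision[1], 2 / 3)
  expect_equal(r$per_class$recall[1], 1 / 2)
  expect_equal(r$per_class$f1[1], 4 / 7)
  expect_equal(r$accuracy, 8 / 11)
})

test_that("the published rust confusion row yields its implied recall", {
  classes <- c("Alternaria leaf spot", "Brown spot", "Frogeye leaf spot",
               "Grey spot", "Health", "Mosaic", "Powdery mildew", "Rust",
               "Scab")
  cm <- matrix(0L, 9, 9, dimnames = list(classes, classes))
  diag(cm) <- 1L  # placeholder support for the other classes
  cm["Rust", ] <- 0L
  cm["Rust", "Rust"] <- 534L
  cm["Rust", "Frogeye leaf spot"] <- 4L
  cm["Rust", "Health"] <- 2L
  cm["Rust", "Scab"] <- 10L
  expect_equal(sum(cm["Rust", ]), 550)  # equals the class's test count
  r <- metrics_from_confusion(cm)
  rust <- r$per_class[r$per_class$class == "Rust", ]
  expect_equal(rust$recall, 534 / 550, tolerance = 1e-12)
  expect_equal(rust$recall, 0.9709, tolerance = 1e-4)
})

test_that("micro precision equals micro recall equals accuracy", {
  set.seed(13)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    cm <- matrix(rpois(K * K, lambda = 5), K, K)
    diag(cm) <- diag(cm) + rpois(K, 20)
    r <- metrics_from_confusion(cm)
    expect_equal(r$micro[["precision"]], r$micro[["recall"]])
    expect_equal(r$micro[["precision"]], r$accuracy)
  }
})

test_that("F1 lies between precision and recall and equals them when equal", {
  set.seed(17)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 8), 3, 3)
    r <- metrics_from_confusion(cm)
    pc <- r$per_class
    ok <- pc$precision + pc$recall > 0
    expect_true(all(pc$f1[ok] >= pmin(pc$precision, pc$recall)[ok] - 1e-12))
    expect_true(all(pc$f1[ok] <= pmax(pc$precision, pc$recall)[ok] + 1e-12))
  }
  cm_eq <- matrix(c(4, 2, 2, 4), 2, 2)
  r <- metrics_from_confusion(cm_eq)
  expect_equal(r$per_class$f1, r$per_class$precision)
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  set.seed(19)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    a <- auc_score(scores, labels)
    # U statistic: #(pos > neg) + 0.5 #(pos == neg), by enumeration
    pos <- scores[labels]; neg <- scores[!labels]
    u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(a, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1) and flip with sign", {
  set.seed(23)
  scores <- rnorm(50)
  labels <- runif(50) < 0.4
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(auc_score(-scores, labels), 1 - auc_score(scores, labels),
               tolerance = 1e-12)
  # perfectly separated scores hit (0, 1)
  s <- c(rep(1, 5), rep(0, 5)); l <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(auc_score(s, l), 1)
  rc2 <- roc_curve(s, l)
  expect_true(any(rc2$fpr == 0 & rc2$tpr == 1))
  expect_error(roc_curve(rnorm(5), rep(TRUE, 5)), "positive and one negative")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(29)
  n <- 1e4
  scores <- rnorm(n)
  labels <- runif(n) < 0.5
  expect_equal(auc_score(scores, labels), 0.5, tolerance = 0.02)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- round(rnorm(60), 1)
  labels <- runif(60) < 0.5
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         direction = "<"))))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-10)
})

test_that("evaluate() reports consistent confusion and per-class AUC", {
  set.seed(37)
  data <- tiny_synthetic_data(n_per_class = 4L, image_size = 32L)$test
  model <- build_model(spec_mfs_compact(length(data$classes),
                                        input_size = 32L))
  # untrained model: some classes are never predicted, so the documented
  # 0/0-precision warning fires
  r <- suppressWarnings(evaluate(model, data))
  expect_equal(unname(rowSums(r$confusion)),
               as.vector(table(factor(data$y, levels = seq_along(data$classes)))))
  expect_true(all(r$per_class$precision >= 0 & r$per_class$precision <= 1))
  expect_true(all(r$auc >= 0 & r$auc <= 1, na.rm = TRUE))
  expect_equal(r$micro[["precision"]], r$accuracy)
})

test_that("perfect predictions give accuracy one and unit AUCs", {
  classes <- c("a", "b", "c")
  y <- rep(1:3, each = 4)
  cm <- confusion_matrix(y, y, classes)
  r <- metrics_from_confusion(cm)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$macro), c(1, 1, 1))
  probs <- matrix(0.05, 3, 12); probs[cbind(y, 1:12)] <- 0.9
  for (k in 1:3) expect_equal(auc_score(probs[k, ], y == k), 1)
})
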