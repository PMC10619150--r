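## Multiclass evaluation: confusion matrix, accuracy, one-vs-rest
## precision / recall / F1 with macro and support-weighted averages, and
## per-class ROC / AUC by threshold sweep with trapezoidal integration.
##
## The headline accuracy is the standard (TP + TN) / total computed as
## correct / total over the confusion matrix.

#' Confusion matrix from labels and predictions
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth integer (1..K) or factor/character true labels.
#' @param pred predicted labels, same coding.
#' @param classes ordered class names.
#' @return K x K integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes) {
  to_idx <- function(v) if (is.numeric(v)) as.integer(v) else match(as.character(v), classes)
  t_i <- to_idx(truth); p_i <- to_idx(pred)
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(t_i)) cm[t_i[i], p_i[i]] <- cm[t_i[i], p_i[i]] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/TN/FN per class, precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean. 0/0 cases yield 0 with a
#' warning and are excluded from the macro averages. Classes with zero
#' support (empty row) are excluded from macro averages as undefined.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return list with `accuracy`, `per_class` data.frame (support, tp, fp,
#'   fn, tn, precision, recall, f1), `macro` and `weighted` averages, and
#'   `micro` (pooled) precision/recall.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  support <- rowSums(cm)
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0 & support > 0)) {
      warning("0/0 in ", what, " for class(es) ",
              paste(rownames(cm)[den == 0 & support > 0], collapse = ", "),
              "; reported as 0", call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  defined <- support > 0
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    support = support, tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    row.names = NULL
  )
  macro <- c(
    precision = mean(precision[defined]),
    recall = mean(recall[defined]),
    f1 = mean(f1[defined])
  )
  w <- support[defined] / sum(support[defined])
  weighted <- c(
    precision = sum(precision[defined] * w),
    recall = sum(recall[defined] * w),
    f1 = sum(f1[defined] * w)
  )
  micro <- c(
    precision = sum(tp) / sum(tp + fp),
    recall = sum(tp) / sum(tp + fn)
  )
  list(
    accuracy = sum(tp) / total,
    per_class = per_class,
    macro = macro,
    weighted = weighted,
    micro = micro,
    confusion = cm
  )
}

#' ROC curve by threshold sweep
#'
#' Sweeps all distinct score thresholds (ties grouped), producing a
#' monotone curve from (0, 0) to (1, 1).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 vector of true positives.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("roc_curve needs at least one positive and one negative label")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  data.frame(
    fpr = c(0, fp / sum(!labels)),
    tpr = c(0, tp / sum(labels))
  )
}

#' Area under the ROC curve (trapezoidal rule)
#' @inheritParams roc_curve
#' @return numeric AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Evaluate a model on a labeled image set
#'
#' Runs the forward pass on `data$x`, builds the confusion matrix and the
#' full metrics report including per-class one-vs-rest ROC/AUC from the
#' softmax scores. The multiclass AUC summary is the unweighted mean of
#' the defined per-class AUCs.
#'
#' @param model a model object.
#' @param data list with `x` (H,W,3,N array), `y` (integer labels) and
#'   `classes`, as returned by [load_manifest_images()].
#' @param batch_size forward-pass batch size.
#' @return a metrics report list (see [metrics_from_confusion()]) with
#'   additional `auc` (per class) and `macro_auc` entries.
#' @export
evaluate <- function(model, data, batch_size = 32L) {
  if (length(data$y) == 0L) stop("empty evaluation set")
  sc <- predict_scores(model, data$x, batch_size)
  pred <- apply(sc$probs, 2, which.max)
  cm <- confusion_matrix(data$y, pred, data$classes)
  rep <- metrics_from_confusion(cm)
  K <- length(data$classes)
  auc <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- data$y == k
    if (any(pos) && !all(pos)) auc[k] <- auc_score(sc$probs[k, ], pos)
    else warning("AUC undefined for class ", data$classes[k], call. = FALSE)
  }
  names(auc) <- data$classes
  rep$auc <- auc
  rep$macro_auc <- mean(auc, na.rm = TRUE)
  rep$probs <- sc$probs
  rep
}
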