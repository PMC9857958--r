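# Classifier evaluation: confusion matrices, per-class precision / recall /
# F1, accuracy, and ROC-AUC by threshold sweep. Conventions: confusion
# rows are truth, columns are predictions, class order c("HCC", "MF-ICC");
# rates whose denominator vanishes are reported as 0 with a warning; the
# headline ROC treats MF-ICC as the positive class.

#' Confusion matrix of truth vs. prediction
#'
#' @param truth,predicted Character/factor vectors over the class set.
#' @param classes Class order (rows = truth, cols = prediction).
#' @return 2x2 (or KxK) integer matrix.
#' @export
confusion_matrix <- function(truth, predicted, classes = .classes) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (anyNA(truth) || anyNA(predicted))
    stopf("labels outside the class set %s", paste(classes, collapse = "/"))
  as.matrix(table(truth = truth, predicted = predicted))
}

#' F1 score from precision and recall
#' @param precision,recall Rates in `[0, 1]`.
#' @return `2 * P * R / (P + R)`, or 0 when the denominator vanishes.
#' @export
f1_score <- function(precision, recall) {
  d <- precision + recall
  ifelse(d > 0, 2 * precision * recall / d, 0)
}

#' Per-class rates and accuracy from a confusion matrix
#'
#' @param cm Square confusion matrix, rows truth and columns prediction,
#'   dimnames optional (class order taken from `classes`).
#' @param classes Class names in row/column order.
#' @return List of class `metrics_report` with `per_class` (data frame of
#'   precision/recall/f1), `accuracy`, `confusion`, and `n`.
#' @export
metrics_from_confusion <- function(cm, classes = .classes) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), nrow(cm) == length(classes))
  dimnames(cm) <- list(truth = classes, predicted = classes)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  rate <- function(num, den, what, cls) {
    if (den == 0) {
      warnf("%s undefined for class %s (empty denominator); reporting 0",
            what, cls)
      return(0)
    }
    num / den
  }
  precision <- vapply(seq_along(classes), function(i)
    rate(tp[i], pred_tot[i], "precision", classes[i]), numeric(1))
  recall <- vapply(seq_along(classes), function(i)
    rate(tp[i], true_tot[i], "recall", classes[i]), numeric(1))
  structure(list(
    per_class = data.frame(class = classes, precision = precision,
                           recall = recall,
                           f1 = f1_score(precision, recall),
                           stringsAsFactors = FALSE),
    accuracy = sum(tp) / sum(cm),
    confusion = cm,
    n = sum(cm)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f on n = %d\n", x$accuracy, x$n))
  if (!is.null(x$auc)) cat(sprintf("macro AUC %.4f\n", x$auc))
  print(x$per_class, row.names = FALSE, digits = 4)
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every unique score as a threshold (prediction positive when
#' `score >= threshold`), collects (FPR, TPR) points, and integrates with
#' the trapezoidal rule. Equals the Mann-Whitney pairwise-concordance
#' statistic (ties counted half).
#'
#' @param scores Numeric vector of positive-class scores.
#' @param labels Vector of class labels.
#' @param positive The positive class.
#' @return List with `points` (data frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "MF-ICC") {
  y <- as.character(labels) == positive
  if (all(y) || all(!y))
    stopf("ROC needs both classes present; got only %s",
          if (all(y)) positive else "the negative class")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(y); N <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / N, numeric(1))
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Full evaluation report from scores
#'
#' @param truth Class labels.
#' @param predicted Predicted labels (argmax).
#' @param scores Optional N x K matrix of class probabilities (columns in
#'   `classes` order) for AUC; per-class AUC treats each class as positive
#'   in turn, and the overall AUC is their macro average. A single-class
#'   truth vector yields `NaN` AUC with a warning.
#' @param classes Class order.
#' @return A `metrics_report` with `auc_per_class` and `auc` added when
#'   scores are given.
#' @export
metrics_report <- function(truth, predicted, scores = NULL,
                           classes = .classes) {
  rep <- metrics_from_confusion(confusion_matrix(truth, predicted, classes),
                                classes)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (length(unique(as.character(truth))) < 2) {
      warnf("single-class test set: AUC undefined, reporting NaN")
      rep$auc_per_class <- setNames(rep(NaN, length(classes)), classes)
      rep$auc <- NaN
    } else {
      rep$auc_per_class <- vapply(seq_along(classes), function(i)
        roc_auc(scores[, i], truth, positive = classes[i])$auc, numeric(1))
      names(rep$auc_per_class) <- classes
      rep$auc <- mean(rep$auc_per_class)
    }
  }
  rep
}

#' Recover the integer confusion matrix behind printed per-class rates
#'
#' Exhaustively searches class sizes up to `max_n` for the smallest integer
#' confusion matrix (rows truth, first class then second) that reproduces
#' the six printed per-class rates and the accuracy to the given number of
#' decimals. Used to turn a published results-table row back into counts
#' that the metric implementations can be checked against.
#'
#' @param rates Named list/vector with `precision_1`, `recall_1`, `f1_1`,
#'   `precision_2`, `recall_2`, `f1_2`, `accuracy` (class 1 = first row).
#' @param max_n Largest class size searched.
#' @param digits Decimals to which the printed rates are rounded.
#' @return 2x2 integer matrix, or an error if no matrix reproduces the row.
#' @export
recover_confusion <- function(rates, max_n = 500, digits = 4) {
  r <- as.list(rates)
  match4 <- function(x, target) round(x, digits) == round(target, digits)
  cand <- function(recall) {
    n <- seq_len(max_n)
    tp <- round(recall * n)
    ok <- tp >= 0 & tp <= n & vapply(seq_along(n), function(i)
      match4(tp[i] / n[i], recall), logical(1))
    cbind(n = n[ok], tp = tp[ok])
  }
  c1 <- cand(r$recall_1)
  c2 <- cand(r$recall_2)
  best <- NULL
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    n1 <- c1[i, "n"]; tp1 <- c1[i, "tp"]
    n2 <- c2[j, "n"]; tp2 <- c2[j, "tp"]
    fp1 <- n2 - tp2  # true class 2 predicted as class 1
    fp2 <- n1 - tp1
    if (tp1 + fp1 == 0 || tp2 + fp2 == 0) next
    p1 <- tp1 / (tp1 + fp1)
    p2 <- tp2 / (tp2 + fp2)
    acc <- (tp1 + tp2) / (n1 + n2)
    if (match4(p1, r$precision_1) && match4(p2, r$precision_2) &&
        match4(acc, r$accuracy) &&
        match4(f1_score(p1, tp1 / n1), r$f1_1) &&
        match4(f1_score(p2, tp2 / n2), r$f1_2)) {
      if (is.null(best) || n1 + n2 < sum(best)) {
        best <- matrix(as.integer(c(tp1, fp1, fp2, tp2)), 2, 2)
      }
    }
  }
  if (is.null(best)) stopf("no confusion matrix up to n = %d reproduces the rates", max_n)
  dimnames(best) <- list(truth = .classes, predicted = .classes)
  best
}

#' Deterministic 2-D embedding of feature vectors
#'
#' Projects items onto their two leading principal components for
#' qualitative inspection of class separability. Deterministic (the seed is
#' accepted for interface stability; the projection itself has no random
#' element, and component signs are fixed by the largest loading).
#'
#' @param features N x D numeric matrix, N >= 5.
#' @param seed Unused beyond interface stability.
#' @return N x 2 matrix of coordinates.
#' @export
embed_2d <- function(features, seed = 0L) {
  features <- as.matrix(features)
  if (nrow(features) < 5)
    stopf("embedding needs at least 5 items, got %d", nrow(features))
  keep <- which(apply(features, 2, function(col) sd(col) > 0))
  if (length(keep) == 0) return(matrix(0, nrow(features), 2))
  p <- prcomp(features[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(2, ncol(p$x))
  out <- matrix(0, nrow(features), 2)
  for (j in seq_len(k)) {
    v <- p$rotation[, j]
    s <- sign(v[which.max(abs(v))])
    out[, j] <- p$x[, j] * s
  }
  out
}
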