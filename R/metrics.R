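#' Matthews correlation coefficient
#'
#' Binary MCC is the confusion-matrix correlation
#' \deqn{(TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' and for more than two classes the K-category correlation coefficient
#' (Gorodkin's R_K) over the confusion matrix. A zero denominator (e.g. a
#' constant predictor) yields 0 by convention. Robust to class imbalance,
#' which is why it drives the wrapper fitness.
#'
#' @param y_true,y_pred equal-length label vectors (any atomic type; the
#'   label universe is the union of both).
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' mcc(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
#' mcc(c(1, 0, 1, 0), c(1, 1, 1, 1))  # 0 (constant predictor)
mcc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  if (length(y_true) == 0) stop("empty label vectors")
  levs <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  cm <- table(factor(y_true, levels = levs), factor(y_pred, levels = levs))
  cm <- matrix(as.numeric(cm), nrow = length(levs))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  tk <- rowSums(cm)   # truth counts
  pk <- colSums(cm)   # prediction counts
  num <- c_ * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Accuracy, balanced accuracy and macro-F1
#'
#' Accuracy is the fraction correct; balanced accuracy the unweighted mean
#' of per-class recalls over classes present in the truth; macro F1 the
#' unweighted mean of per-class F1 over the label universe (a class absent
#' from both truth and prediction would contribute 0, but the universe is
#' taken from the data so this arises only with explicit factor levels).
#'
#' @inheritParams mcc
#' @return Named list: `accuracy`, `balanced_accuracy`, `f1_macro`.
#' @export
metric_suite <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  if (length(y_true) == 0) stop("empty label vectors")
  universe <- if (is.factor(y_true)) {
    sort(unique(c(levels(y_true), as.character(y_pred))))
  } else {
    sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  yt <- factor(y_true, levels = universe)
  yp <- factor(y_pred, levels = universe)
  cm <- table(yt, yp)
  acc <- sum(diag(cm)) / length(yt)
  present <- rowSums(cm) > 0
  recalls <- diag(cm)[present] / rowSums(cm)[present]
  f1 <- vapply(seq_along(universe), function(k) {
    tp <- cm[k, k]
    denom <- 2 * tp + sum(cm[, k]) - tp + sum(cm[k, ]) - tp
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  list(accuracy = acc,
       balanced_accuracy = mean(recalls),
       f1_macro = mean(f1))
}
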