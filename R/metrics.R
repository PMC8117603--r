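## ROC / PR evaluation of pooled classifier scores.

## accepts logical, 0/1 numeric, or character/factor labels where "lncRNA"
## is the positive class
as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(as.integer(labels == "lncRNA"))
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels)
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the unique score values (ties collapsed) and
#' returns the (FPR, TPR) points, anchored at (0, 0) and ending at (1, 1),
#' plus the trapezoidal area. With ties handled by the trapezoid, the area
#' equals the pair statistic `P(score+ > score-) + 0.5 P(score+ = score-)`.
#'
#' @param labels Class labels: logical, 0/1, or character with `"lncRNA"` as
#'   the positive class. Both classes must be present.
#' @param scores Numeric scores, higher meaning more positive.
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(.9, .8, .7, .6))$auc  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  cm <- sweep_confusion(labels, scores)
  tpr <- c(0, cm$tp / cm$P)
  fpr <- c(0, cm$fp / cm$N)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Precision and recall at the same thresholds as [roc_auc()]; the area is
#' the step-wise (precision-weighted) sum `sum_i (R_i - R_{i-1}) * P_i` with
#' `R_0 = 0`, i.e. average precision. When every score is identical the area
#' equals the class prevalence.
#'
#' @inheritParams roc_auc
#' @return List with `points` (data frame `recall`, `precision`) and `aupr`.
#' @export
pr_aupr <- function(labels, scores) {
  cm <- sweep_confusion(labels, scores)
  recall <- cm$tp / cm$P
  precision <- cm$tp / (cm$tp + cm$fp)
  aupr <- sum((recall - c(0, recall[-length(recall)])) * precision)
  list(points = data.frame(recall = recall, precision = precision), aupr = aupr)
}

## cumulative TP/FP at each unique score threshold, descending
sweep_confusion <- function(labels, scores) {
  y <- as_binary_label(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  P <- sum(y); N <- length(y) - P
  if (P == 0L || N == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  cut <- cumsum(rle(s)$lengths)          # last index of each tie block
  tp <- cumsum(y)[cut]
  fp <- cut - tp
  list(tp = tp, fp = fp, P = P, N = N)
}
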