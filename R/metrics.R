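#' Confusion counts
#'
#' Damaging (disease-causing) is the positive class: TP = damaging predicted
#' damaging, TN = neutral predicted neutral, FP = neutral predicted damaging,
#' FN = damaging predicted neutral.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return object of class `confusion`.
#' @export
confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion")
}

#' Confusion from label vectors
#'
#' @param truth,predicted vectors with values "damaging"/"neutral".
#' @export
confusion_from_labels <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion(tp = sum(truth == "damaging" & predicted == "damaging"),
            tn = sum(truth == "neutral" & predicted == "neutral"),
            fp = sum(truth == "neutral" & predicted == "damaging"),
            fn = sum(truth == "damaging" & predicted == "neutral"))
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), accuracy (TP+TN)/n and the Matthews correlation coefficient
#' (TPxTN - FPxFN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). Counts are
#' integers, so the arithmetic is exact up to the final division. A metric
#' whose denominator is 0 (including MCC with any zero marginal) is `NA`.
#'
#' @param c a `confusion`.
#' @return object of class `eval_report` (a list of the metrics plus the
#'   confusion and `n`).
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion"))
  # double precision: count products overflow 32-bit integers, and integers
  # up to 2^53 stay exact in doubles
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion: no samples evaluated")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den2 <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  structure(list(
    confusion = c, n = n,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp),
    accuracy = (tp + tn) / n,
    mcc = if (mcc_den2 == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den2),
    auc = NA_real_
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.0f%%", 100 * v)
  two <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(
    "n=%d  sensitivity=%s  specificity=%s  precision=%s  accuracy=%s  MCC=%s  AUC=%s\n",
    x$n, pct(x$sensitivity), pct(x$specificity), pct(x$precision),
    pct(x$accuracy), two(x$mcc), two(x$auc)))
  invisible(x)
}

#' ROC area under the curve
#'
#' Trapezoidal area over all score thresholds with tied scores averaged —
#' numerically identical to the Mann-Whitney pairwise statistic
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric ranking values (higher = more damaging-like).
#' @param labels "damaging"/"neutral" vector.
#' @param positive label of the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "damaging") {
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes are required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Sensitivity and 1-specificity at every distinct score threshold, for
#' plotting or TSV export.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `sensitivity`, `fpr`.
#' @export
roc_points <- function(scores, labels, positive = "damaging") {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  out <- lapply(c(Inf, thr), function(t) {
    call_pos <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(call_pos & pos) / np,
               fpr = sum(call_pos & !pos) / nn)
  })
  do.call(rbind, out)
}

#' Format an evaluation report the way performance tables are printed
#'
#' Percentages to whole numbers, MCC and AUC to two decimals.
#'
#' @param report an `eval_report`.
#' @return named character vector.
#' @export
format_report <- function(report) {
  pct <- function(v) if (is.na(v)) NA_character_ else sprintf("%.0f%%", 100 * v)
  two <- function(v) if (is.na(v)) NA_character_ else sprintf("%.2f", v)
  c(sensitivity = pct(report$sensitivity), specificity = pct(report$specificity),
    precision = pct(report$precision), accuracy = pct(report$accuracy),
    mcc = two(report$mcc), auc = two(report$auc))
}
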