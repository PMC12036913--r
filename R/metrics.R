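# Binary classification metric suite: confusion counts at a threshold,
# the six scalar metrics, and the ROC / AUC.

#' Evaluate binary predictions
#'
#' Computes the confusion counts at `threshold` (predicted positive iff
#' score > threshold, so a score exactly at the threshold is negative),
#' sensitivity, specificity, Matthews correlation coefficient, accuracy,
#' precision and F1 from the standard confusion-matrix formulas, and the
#' area under the ROC curve by trapezoidal integration over all distinct
#' score thresholds (tied scores grouped). Any metric with a zero
#' denominator is reported as 0 (the convention needed for degenerate
#' folds); MCC uses the same convention.
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `sep_eval`: list with `counts`
#'   (TP/TN/FP/FN), `metrics` (SN, SP, MCC, ACC, PRE, F1, AUC) and `roc`
#'   (data.frame of FPR/TPR points).
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1))) stop("y_true must be binary 0/1")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y_true == 1)
  tn <- sum(pred == 0L & y_true == 0)
  fp <- sum(pred == 1L & y_true == 0)
  fn <- sum(pred == 0L & y_true == 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, fp + tn)
  acc <- safe_div(tp + tn, tp + fp + fn + tn)
  pre <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else ((tp * tn) - (fp * fn)) / mcc_den
  roc <- roc_points(y_true, scores)
  auc <- trapezoid_auc(roc$fpr, roc$tpr)
  structure(list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    metrics = c(SN = sn, SP = sp, MCC = mcc, ACC = acc,
                PRE = pre, F1 = f1, AUC = auc),
    roc = roc,
    threshold = threshold
  ), class = "sep_eval")
}

# ROC curve over all distinct thresholds, scores descending; ties grouped.
roc_points <- function(y_true, scores) {
  o <- order(scores, decreasing = TRUE)
  y <- y_true[o]; s <- scores[o]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1)[grp_last]
  fp <- cumsum(y == 0)[grp_last]
  data.frame(
    fpr = c(0, if (n_neg > 0) fp / n_neg else fp * 0),
    tpr = c(0, if (n_pos > 0) tp / n_pos else tp * 0)
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' @export
print.sep_eval <- function(x, ...) {
  cat("Binary classification report (threshold ", x$threshold, ")\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = "  "), "\n", sep = "")
  cat("  ", paste(names(x$metrics), sprintf("%.4f", x$metrics), sep = "=",
                  collapse = "  "), "\n", sep = "")
  invisible(x)
}
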