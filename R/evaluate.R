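# Confusion-summary arithmetic and ROC curves. Percentages are truncated
# (floored) at the requested precision, the convention under which every
# published figure of this kind (52.9, 94.11, 99.8, ...) is reproduced
# simultaneously; rounding would not be.

#' Confusion summary of a screening run
#'
#' @param total number of samples screened (N).
#' @param positives number of true events present (P).
#' @param predicted_positive number of samples called positive.
#' @param true_positive calls that are true events (TP); false positives are
#'   derived as `predicted_positive - TP`.
#' @export
confusion_summary <- function(total, positives, predicted_positive,
                              true_positive) {
  stopifnot(positives <= total, true_positive <= positives,
            true_positive <= predicted_positive)
  structure(list(total = total, positives = positives,
                 predicted_positive = predicted_positive,
                 true_positive = true_positive,
                 false_positive = predicted_positive - true_positive),
            class = "confusion_summary")
}

#' Confusion summary from calls and truth labels
#'
#' @param calls character vector of `"WT"`/`"delta14"` calls.
#' @param truth character vector of true labels (positives = `"delta14"`).
#' @export
confusion_from_calls <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  confusion_summary(length(truth), sum(truth == "delta14"),
                    sum(calls == "delta14"),
                    sum(calls == "delta14" & truth == "delta14"))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "confusion_summary: N=%d P=%d predicted=%d TP=%d FP=%d (sens %s%%, spec %s%%)\n",
    x$total, x$positives, x$predicted_positive, x$true_positive,
    x$false_positive, format(sensitivity_pct(x)),
    format(specificity_overall_pct(x))))
  invisible(x)
}

trunc_pct <- function(x, digits) floor(x * 10^digits) / 10^digits

#' Sensitivity as a truncated percentage
#'
#' `100 * TP / P`, truncated (floored) at `digits` decimals.
#'
#' @param cs a [confusion_summary()].
#' @param digits decimal places kept.
#' @export
sensitivity_pct <- function(cs, digits = 1L) {
  if (cs$positives == 0L) stopf("sensitivity undefined: no true positives exist")
  trunc_pct(100 * cs$true_positive / cs$positives, digits)
}

#' Specificity over all screened samples, truncated percentage
#'
#' The cohort-screening convention `100 * (N - FP) / N`: the fraction of the
#' whole screened set not flagged falsely. See
#' [specificity_classical_pct()] for the textbook `TN / (TN + FP)` variant;
#' the two agree when the cohort contains no true events.
#'
#' @inheritParams sensitivity_pct
#' @export
specificity_overall_pct <- function(cs, digits = 1L) {
  stopifnot(cs$total > 0L)
  trunc_pct(100 * (cs$total - cs$false_positive) / cs$total, digits)
}

#' Classical specificity `TN / (TN + FP)`, truncated percentage
#' @inheritParams sensitivity_pct
#' @export
specificity_classical_pct <- function(cs, digits = 1L) {
  negatives <- cs$total - cs$positives
  if (negatives == 0L) stopf("specificity undefined: no negatives")
  trunc_pct(100 * (negatives - cs$false_positive) / negatives, digits)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over all observed scores, recording
#' true/false positive rates; the AUC is the trapezoid-rule area, which
#' equals the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary truth: 0/1, logical, or `"WT"`/`"delta14"`.
#' @return object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "delta14"
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stopf("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(!y))
  thresholds <- c(Inf, scores[o][keep])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
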