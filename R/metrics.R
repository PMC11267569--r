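# Binary-classification metric suite: accuracy, sensitivity, specificity,
# Matthews correlation coefficient, and rank-based AUC. Accuracy/SN/SP/AUC
# are reported as percentages (the field's reporting convention); MCC on its
# natural [-1, 1] scale. Undefined ratios (zero denominators) are reported
# as NA, never silently as 0.

#' Metrics from a confusion matrix
#'
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP\cdot TN - FP\cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @param auc Optional AUC in `[0, 1]` to attach (reported as a percentage).
#' @return A `metrics_report`: list with `accuracy`, `sensitivity`,
#'   `specificity` (percent), `mcc`, `auc` (percent or `NA`), and
#'   `confusion` (named counts). Undefined metrics are `NA`.
#' @examples
#' confusion_metrics(tp = 186, fn = 14, tn = 192, fp = 8)
#' @export
confusion_metrics <- function(tp, tn, fp, fn, auc = NA_real_) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "enhancaps_parameter_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort("Confusion matrix is empty.", class = "enhancaps_parameter_error")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / total
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_
  structure(
    list(accuracy = 100 * acc, sensitivity = 100 * sn, specificity = 100 * sp,
         mcc = mcc, auc = if (is.na(auc)) NA_real_ else 100 * auc,
         confusion = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("Confusion: TP=%d TN=%d FP=%d FN=%d\n",
              cm[["tp"]], cm[["tn"]], cm[["fp"]], cm[["fn"]]))
  fmt <- function(v, pct = TRUE) {
    if (is.na(v)) "undefined" else sprintf(if (pct) "%.1f%%" else "%.3f", v)
  }
  cat(sprintf("ACC %s | SN %s | SP %s | MCC %s | AUC %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$mcc, FALSE), fmt(x$auc)))
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "mcc", "auc"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$mcc, x$auc))
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  cm <- as.list(x$confusion)
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, mcc = x$mcc, auc = x$auc,
         tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
}

#' Area under the ROC curve (rank-sum form)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted 1/2 — the Mann-Whitney statistic computed
#' from midranks, identical to brute-force pair enumeration.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels, same length as `scores`.
#' @param positive The label counted as positive; defaults to `TRUE` for
#'   logicals, otherwise must be supplied when labels are not 0/1.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.4, 0.35, 0.8), c(1, 1, 0, 0), positive = 1)
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE
    else if (all(labels %in% c(0, 1))) 1
    else abort("Supply `positive` for non-binary labels.",
               class = "enhancaps_parameter_error")
  }
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC is undefined with a single class present.",
          class = "enhancaps_undefined_value_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
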