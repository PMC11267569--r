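# ggplot2 visualisations for the main result types.

#' @describeIn fcgr_rasterize Heatmap of an FCGR image (row 1 at the top,
#'   matching the CGR orientation: T quadrant upper right).
#' @param object An `fcgr_image`.
#' @param ... Unused.
#' @method autoplot fcgr_image
#' @export
autoplot.fcgr_image <- function(object, ...) {
  n <- attr(object, "resolution")
  # column-major: value (row, col) sits at row + (col - 1) * n
  df <- tibble(row = rep(seq_len(n), times = n),
               col = rep(seq_len(n), each = n),
               count = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "count",
                  title = sprintf("FCGR %d x %d (%d points)", n, n,
                                  attr(object, "total_points")))
}

#' @describeIn caps_train Training-loss trajectory of a fitted model.
#' @param object A `caps_model`.
#' @param ... Unused.
#' @method autoplot caps_model
#' @export
autoplot.caps_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean margin loss",
                  title = sprintf("%s vs %s (%s head)",
                                  object$classes[["positive"]],
                                  object$classes[["negative"]],
                                  object$config$head))
}

#' ROC curve data for scored records
#'
#' Convenience table of (FPR, TPR) pairs at every threshold, for plotting
#' the ROC curve whose area [auc_score()] computes.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Class labels.
#' @param positive Label counted as positive (see [auc_score()]).
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE else 1
  }
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1L)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1L))
  )
}
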