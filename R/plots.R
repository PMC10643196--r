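#' Bland-Altman plot
#'
#' Difference against pairwise average with the mean-difference line (solid)
#' and the 95% limits of agreement (dashed).
#'
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Average of predicted and measured METs",
                  y = "Predicted - measured (METs)",
                  title = sprintf("Bland-Altman: %d/%d (%.1f%%) outside the LoA",
                                  object$n_outside, object$n,
                                  100 * object$frac_outside)) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- dplyr::arrange(object$roc, .data$fpr, .data$tpr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (walk misclassified)",
                  y = "Sensitivity (run detected)",
                  title = sprintf("ROC of window Mean, AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Per-speed error plot of an evaluation report
#'
#' RMSE by treadmill speed, colored by gait when available.
#'
#' @param object An `eval_report` with a per-speed table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$per_speed))
    abort("This report has no per-speed table; evaluate with `speed_kmh` in `group_keys`.")
  ggplot2::ggplot(object$per_speed,
                  ggplot2::aes(x = factor(.data$speed_kmh), y = .data$rmse)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Treadmill speed (km/h)", y = "RMSE (METs)",
                  title = sprintf("Per-speed prediction error (overall RMSE %.2f METs)",
                                  object$overall$rmse)) +
    ggplot2::theme_minimal()
}

#' Window-Mean scatter by speed
#'
#' The diagnostic view behind the walk/run cut-point: window Means plotted
#' against treadmill speed, colored by gait. With a fitted cut-point the
#' threshold is drawn as a horizontal line.
#'
#' @param data Feature table with `speed_kmh`, `gait` and a Mean column.
#' @param mean_col Mean column (default `"mean_vm"`).
#' @param cutoff Optional `cutoff_model` whose threshold is drawn.
#' @return A ggplot.
#' @export
plot_mean_scatter <- function(data, mean_col = "mean_vm", cutoff = NULL) {
  miss <- setdiff(c("speed_kmh", "gait", mean_col), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$speed_kmh, y = .data[[mean_col]],
                                    color = .data$gait)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 0.9) +
    ggplot2::labs(x = "Treadmill speed (km/h)", y = "Window Mean (g)",
                  color = "Gait") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff$threshold,
                                 linetype = "dashed")
  p
}
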