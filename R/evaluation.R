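#' Root mean square error of METs predictions
#'
#' `sqrt(mean((predicted - measured)^2))`, the headline accuracy metric of
#' all the predictors in this package.
#'
#' @param predicted,measured Equal-length numeric vectors of METs.
#' @return RMSE in METs.
#' @export
rmse <- function(predicted, measured) {
  check_pairs(predicted, measured)
  sqrt(mean((predicted - measured)^2))
}

#' Bias of METs predictions
#'
#' Two conventions are in circulation and both are implemented. The
#' `"relative"` mode is `mean((predicted - measured) / measured)` — a
#' unitless fractional error requiring `measured != 0`. The `"absolute"`
#' mode is `mean(predicted - measured)` in METs. Reports produced by
#' [evaluate_predictions()] always label which mode they carry.
#'
#' @param predicted,measured Equal-length numeric vectors of METs.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return Mean bias (unitless for relative, METs for absolute).
#' @export
bias <- function(predicted, measured, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  check_pairs(predicted, measured)
  if (mode == "relative") {
    if (any(measured == 0))
      abort("Relative bias requires `measured` != 0 everywhere.")
    mean((predicted - measured) / measured)
  } else {
    mean(predicted - measured)
  }
}

check_pairs <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    abort("`predicted` and `measured` must have equal lengths.")
  if (length(predicted) == 0) abort("Need at least one pair.")
  assert_finite(predicted, "predicted")
  assert_finite(measured, "measured")
  invisible(NULL)
}

#' Bland-Altman agreement analysis
#'
#' Assesses agreement between predicted and measured METs through the
#' differences `d = predicted - measured`: the mean difference and the 95%
#' limits of agreement `mean(d) +/- 1.96 sd(d)` (sd with denominator n-1;
#' the multiplier is the fixed normal quantile, not a small-sample t).
#' Points strictly outside either limit are counted; points exactly on a
#' limit count as inside.
#'
#' @param predicted,measured Equal-length numeric vectors of METs (>= 3
#'   pairs).
#' @return An object of class `bland_altman`: `$mean_diff`, `$loa_low`,
#'   `$loa_high`, `$n_outside`, `$frac_outside`, `$n`, and `$points`
#'   (tibble of pairwise average vs difference for plotting).
#' @examples
#' ba <- bland_altman(c(3, 4, 5), c(4, 4, 4))
#' ba$mean_diff
#' @export
bland_altman <- function(predicted, measured) {
  check_pairs(predicted, measured)
  if (length(predicted) < 3) abort("Bland-Altman needs at least 3 pairs.")
  d <- predicted - measured
  m <- mean(d)
  s <- sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  outside <- d < lo | d > hi
  structure(
    list(mean_diff = m, loa_low = lo, loa_high = hi,
         n_outside = sum(outside), frac_outside = mean(outside),
         n = length(d),
         points = tibble(average = (predicted + measured) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.3f METs, 95%% LoA [%.3f, %.3f], %d/%d (%.2f%%) outside\n",
    x$mean_diff, x$loa_low, x$loa_high, x$n_outside, x$n,
    100 * x$frac_outside))
  invisible(x)
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, loa_low = x$loa_low, loa_high = x$loa_high,
         n_outside = x$n_outside, frac_outside = x$frac_outside, n = x$n)
}

#' Full evaluation report for a METs predictor
#'
#' Computes the overall RMSE and Bias, a Bland-Altman analysis, and RMSE/Bias
#' broken down by gait and by treadmill speed (ordered by speed), from a
#' table of paired predictions. Per-group bias rows also carry the standard
#' deviation of the per-window bias terms (`bias_sd`, labeled as an SD).
#'
#' @param data Data frame with prediction, measurement and label columns.
#' @param predicted_col,measured_col Column names of the paired METs values.
#' @param group_keys Label columns for the sub-tables; any of `"gait"`,
#'   `"speed_kmh"` present in `data` (default both).
#' @param bias_mode Passed to [bias()]; reports label the mode.
#' @return An object of class `eval_report`: `$overall` (one-row tibble with
#'   `rmse`, `bias`, `n`), `$per_gait`, `$per_speed`, `$bland_altman`,
#'   `$bias_mode`.
#' @export
evaluate_predictions <- function(data, predicted_col = "predicted",
                                 measured_col = "measured_mets",
                                 group_keys = c("gait", "speed_kmh"),
                                 bias_mode = c("relative", "absolute")) {
  bias_mode <- match.arg(bias_mode)
  miss <- setdiff(c(predicted_col, measured_col), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  bad_keys <- setdiff(group_keys, c("gait", "speed_kmh"))
  if (length(bad_keys) > 0)
    abort(paste0("Unknown group key(s): ", paste(bad_keys, collapse = ", "), "."))
  pred <- data[[predicted_col]]
  meas <- data[[measured_col]]

  summarise_group <- function(df) {
    p <- df[[predicted_col]]; m <- df[[measured_col]]
    terms <- if (bias_mode == "relative") (p - m) / m else p - m
    tibble(rmse = rmse(p, m), bias = bias(p, m, bias_mode),
           bias_sd = sd(terms), n = nrow(df))
  }

  by_key <- function(key) {
    if (!key %in% group_keys || !key %in% names(data)) return(NULL)
    data |>
      dplyr::group_by(.data[[key]]) |>
      dplyr::group_modify(~ summarise_group(.x)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data[[key]])
  }

  structure(
    list(overall = tibble(rmse = rmse(pred, meas),
                          bias = bias(pred, meas, bias_mode),
                          n = length(pred)),
         per_gait = by_key("gait"),
         per_speed = by_key("speed_kmh"),
         bland_altman = if (length(pred) >= 3) bland_altman(pred, meas) else NULL,
         bias_mode = bias_mode),
    class = "eval_report")
}

#' Evaluate a fitted METs model on a feature table
#'
#' Runs the model's [predict()] method over `data` and summarizes the errors
#' with [evaluate_predictions()]. Works with any predictor in the package:
#' closed-form regressions (`ee_model`/`ee_fit`, which read the Mean from
#' `mean_col`), networks (`ann_model`) and the composite `two_stage_model`.
#'
#' @param model A fitted predictor.
#' @param data Feature table with measured METs and label columns.
#' @param measured_col Measured-METs column (default `"measured_mets"`).
#' @param mean_col Mean column used by closed-form regressions (default
#'   `"mean_vm"`).
#' @param ... Passed to [evaluate_predictions()] (`group_keys`,
#'   `bias_mode`).
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, data, measured_col = "measured_mets",
                           mean_col = "mean_vm", ...) {
  pred <- if (inherits(model, c("ee_model", "ee_fit"))) {
    if (!mean_col %in% names(data))
      abort(paste0("Missing Mean column `", mean_col, "`."))
    predict(model, data[[mean_col]])
  } else {
    predict(model, data)
  }
  data$.predicted <- pred
  evaluate_predictions(data, predicted_col = ".predicted",
                       measured_col = measured_col, ...)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> (bias mode: %s)\n", x$bias_mode))
  cat(sprintf("  overall: RMSE %.3f METs, Bias %.4f, n = %d\n",
              x$overall$rmse, x$overall$bias, x$overall$n))
  if (!is.null(x$per_gait)) {
    for (i in seq_len(nrow(x$per_gait)))
      cat(sprintf("  %s: RMSE %.3f, Bias %.4f (SD %.4f), n = %d\n",
                  x$per_gait$gait[i], x$per_gait$rmse[i], x$per_gait$bias[i],
                  x$per_gait$bias_sd[i], x$per_gait$n[i]))
  }
  if (!is.null(x$bland_altman)) { cat("  "); print(x$bland_altman) }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-speed error table (falling back to per-gait,
#'   then overall). `glance()`: a one-row overall summary including the
#'   Bland-Altman fields.
#' @export
tidy.eval_report <- function(x, ...) {
  if (!is.null(x$per_speed)) return(x$per_speed)
  if (!is.null(x$per_gait)) return(x$per_gait)
  x$overall
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  out <- x$overall
  out$bias_mode <- x$bias_mode
  if (!is.null(x$bland_altman)) {
    ba <- glance(x$bland_altman)
    out$ba_mean_diff <- ba$mean_diff
    out$ba_loa_low <- ba$loa_low
    out$ba_loa_high <- ba$loa_high
    out$ba_frac_outside <- ba$frac_outside
  }
  out
}
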