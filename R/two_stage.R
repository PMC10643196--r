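#' ROC analysis of the walk/run window Mean
#'
#' Builds the ROC curve for discriminating running from walking by
#' thresholding the window Mean. Candidate thresholds are the midpoints
#' between consecutive sorted unique Means plus `-Inf`/`+Inf` sentinels;
#' at each threshold, sensitivity is `P(Mean > thr | run)` and the false
#' positive rate is `P(Mean > thr | walk)`. The area under the curve is
#' computed by trapezoidal integration, which equals the Mann-Whitney
#' statistic with ties counted one half.
#'
#' @param data Data frame with a window-Mean column and a gait label column,
#'   or `NULL` if `means`/`labels` are given directly.
#' @param mean_col,gait_col Column names (defaults `"mean"`, `"gait"`).
#' @param means,labels Optional numeric/character vectors used instead of
#'   `data`.
#' @param positive Label of the positive class (default `"run"`).
#' @return An object of class `roc_result`: `$roc` (tibble with `threshold`,
#'   `tpr`, `fpr`), `$auc`, `$positive`, `$n_pos`, `$n_neg`.
#' @examples
#' d <- tibble::tibble(mean = c(0.1, 0.2, 0.3, 0.4),
#'                     gait = c("walk", "walk", "run", "run"))
#' roc_analysis(d)$auc  # 1
#' @export
roc_analysis <- function(data = NULL, mean_col = "mean", gait_col = "gait",
                         means = NULL, labels = NULL, positive = "run") {
  if (!is.null(data)) {
    miss <- setdiff(c(mean_col, gait_col), names(data))
    if (length(miss) > 0)
      abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
    means <- data[[mean_col]]
    labels <- as.character(data[[gait_col]])
  }
  assert_finite(means, "means")
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0)
    abort("Both classes must be present for ROC analysis.")

  u <- sort(unique(means))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  pos_sorted <- sort(means[is_pos])
  neg_sorted <- sort(means[!is_pos])
  # midpoint thresholds never coincide with data values, so > and >= agree
  tpr <- (n_pos - findInterval(thr, pos_sorted)) / n_pos
  fpr <- (n_neg - findInterval(thr, neg_sorted)) / n_neg

  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)

  structure(
    list(roc = tibble(threshold = thr, tpr = tpr, fpr = fpr),
         auc = auc, positive = positive, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d %s / %d other, %d thresholds)\n",
              x$auc, x$n_pos, x$positive, x$n_neg, nrow(x$roc)))
  invisible(x)
}

#' Youden-index cut-point on the window Mean
#'
#' Picks the threshold maximizing the Youden index `J = tpr - fpr`
#' (sensitivity + specificity - 1). Because the candidate thresholds are
#' midpoints between adjacent observed Means, a perfectly separable sample
#' has a unique maximum at the midpoint of the separating gap — the
#' maximum-margin cut. When several thresholds tie at the maximum J, the
#' largest is returned.
#'
#' @param roc A `roc_result` from [roc_analysis()].
#' @return An object of class `cutoff_model`: `$threshold` (Mean, g),
#'   `$youden_j`, `$auc`, `$positive`.
#' @examples
#' d <- tibble::tibble(mean = c(0.1, 0.2, 0.3, 0.4),
#'                     gait = c("walk", "walk", "run", "run"))
#' youden_cutoff(roc_analysis(d))$threshold  # 0.25
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result")) abort("`roc` must come from `roc_analysis()`.")
  j <- roc$roc$tpr - roc$roc$fpr
  finite <- is.finite(roc$roc$threshold)
  cand <- which(j == max(j[finite]) & finite)
  thr <- max(roc$roc$threshold[cand])
  structure(
    list(threshold = thr, youden_j = max(j[finite]), auc = roc$auc,
         positive = roc$positive),
    class = "cutoff_model")
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf("<cutoff_model> Mean > %.5f -> %s (J = %.3f, AUC = %.4f)\n",
              x$threshold, x$positive, x$youden_j, x$auc))
  invisible(x)
}

#' Classify windows as walking or running
#'
#' Applies the fitted cut-point: a window is classified as running iff its
#' Mean is strictly greater than the threshold; a Mean exactly on the
#' boundary is classified as walking.
#'
#' @param mean Numeric vector of window Means.
#' @param cutoff A `cutoff_model` from [youden_cutoff()].
#' @return Character vector of `"walk"` / `"run"` labels.
#' @export
classify_gait <- function(mean, cutoff) {
  if (!inherits(cutoff, "cutoff_model"))
    abort("`cutoff` must come from `youden_cutoff()`.")
  ifelse(mean > cutoff$threshold, cutoff$positive, "walk")
}

#' Train the two-stage walk/run METs model
#'
#' The composite model of the pipeline: a Youden cut-point on the
#' (preprocessed-VM) window Mean classifies each window as walking or
#' running, and a gait-specific network predicts METs. The cut-point is
#' fitted on the training Means; the walking and running networks are
#' trained on their respective gait strata of the same training split, each
#' with its own feature normalizer. Reference configurations: walking 9
#' hidden neurons / decay 0.8, running 4 hidden neurons / decay 0.7.
#'
#' @param data Training feature table with gait labels, measured METs, the
#'   Mean column and the network feature columns.
#' @param walk_config,run_config [ann_config()]s for the two strata.
#' @param feature_cols Network input columns (default [feature_names()]).
#' @param target_col Measured-METs column (default `"measured_mets"`).
#' @param mean_col Window-Mean column used by the cut-point (default
#'   `"mean_vm"`, the preprocessed-VM Mean).
#' @param gait_col Gait label column (default `"gait"`).
#' @return An object of class `two_stage_model`: `$cutoff`, `$walk_model`,
#'   `$run_model` plus the column names used.
#' @export
train_two_stage <- function(data,
                            walk_config = ann_config(hidden_n = 9, weight_decay = 0.8),
                            run_config = ann_config(hidden_n = 4, weight_decay = 0.7),
                            feature_cols = feature_names(),
                            target_col = "measured_mets",
                            mean_col = "mean_vm", gait_col = "gait") {
  miss <- setdiff(c(feature_cols, target_col, mean_col, gait_col), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  gait <- as.character(data[[gait_col]])
  if (sum(gait == "walk") < 2 || sum(gait == "run") < 2)
    abort("Both gait strata need at least 2 training windows.")

  roc <- roc_analysis(data, mean_col = mean_col, gait_col = gait_col)
  cutoff <- youden_cutoff(roc)
  walk_model <- train_ann(data[gait == "walk", , drop = FALSE],
                          feature_cols, target_col, walk_config)
  run_model <- train_ann(data[gait == "run", , drop = FALSE],
                         feature_cols, target_col, run_config)
  structure(
    list(cutoff = cutoff, walk_model = walk_model, run_model = run_model,
         feature_cols = feature_cols, target_col = target_col,
         mean_col = mean_col, gait_col = gait_col),
    class = "two_stage_model")
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model>\n  cutoff: "); print(x$cutoff)
  cat("  walk: "); print(x$walk_model)
  cat("  run:  "); print(x$run_model)
  invisible(x)
}

#' Predict METs with the two-stage model
#'
#' Each window is classified by its Mean and dispatched to the matching
#' gait-specific network; the per-window prediction equals that network's
#' lone prediction exactly.
#'
#' @param object A `two_stage_model` from [train_two_stage()].
#' @param newdata Feature table with the model's Mean column and network
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted METs.
#' @export
predict.two_stage_model <- function(object, newdata, ...) {
  if (!object$mean_col %in% names(newdata))
    abort(paste0("Missing Mean column `", object$mean_col, "`."))
  cls <- classify_gait(newdata[[object$mean_col]], object$cutoff)
  out <- numeric(nrow(newdata))
  is_run <- cls == object$cutoff$positive
  if (any(is_run))
    out[is_run] <- predict(object$run_model, newdata[is_run, , drop = FALSE])
  if (any(!is_run))
    out[!is_run] <- predict(object$walk_model, newdata[!is_run, , drop = FALSE])
  out
}

#' @export
glance.two_stage_model <- function(x, ...) {
  tibble(threshold = x$cutoff$threshold, youden_j = x$cutoff$youden_j,
         auc = x$cutoff$auc,
         walk_hidden_n = ncol(x$walk_model$W1),
         walk_decay = x$walk_model$config$weight_decay,
         run_hidden_n = ncol(x$run_model$W1),
         run_decay = x$run_model$config$weight_decay)
}
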