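#' Names of the nine window summary features
#'
#' The feature vector fed to the neural-network regressors: mean, standard
#' deviation, max, min and the 10th/25th/50th/75th/90th percentiles of the VM
#' samples in one window.
#'
#' @return Character vector of length 9.
#' @export
feature_names <- function() {
  c("mean", "sd", "max", "min", "p10", "p25", "p50", "p75", "p90")
}

#' Segment a VM series into fixed non-overlapping windows
#'
#' Cuts each bout of a VM series into consecutive, non-overlapping windows of
#' `duration_s` seconds. Windows never span two bouts: the series is grouped
#' by the label columns present (`subject`, `speed_kmh`, `gait`) and each bout
#' is windowed independently. A trailing partial window is discarded.
#'
#' @param vm Data frame with columns `t` and `vm` (from
#'   [preprocess_stream()] or [raw_vm_stream()]) plus optional label columns.
#' @param duration_s Window length in seconds; one of 10, 30 or 60
#'   (default 60).
#' @param rate Sampling rate in Hz (default 100).
#' @return A tibble with one row per window: label columns, `window_start`
#'   (seconds), `duration_s`, and a list-column `samples` of VM values.
#'   Bouts shorter than one window contribute no rows (with a warning when
#'   the whole input is shorter than one window).
#' @examples
#' vm <- tibble::tibble(t = seq(0, 239.99, by = 0.01), vm = abs(sin(1:24000)))
#' nrow(segment_windows(vm, 60))  # 4
#' @export
segment_windows <- function(vm, duration_s = 60, rate = 100) {
  if (!all(c("t", "vm") %in% names(vm)))
    abort("`vm` must have columns `t` and `vm`.")
  if (!duration_s %in% c(10, 30, 60))
    abort("`duration_s` must be one of 10, 30, 60.")
  n_per <- as.integer(round(duration_s * rate))
  if (n_per < 2) abort("`duration_s * rate` must be at least 2.")
  keys <- label_cols(vm)

  cut_bout <- function(df) {
    n_win <- nrow(df) %/% n_per
    if (n_win == 0) return(NULL)
    idx <- seq_len(n_win * n_per)
    win <- (idx - 1L) %/% n_per
    tibble(
      window_start = df$t[seq(1L, by = n_per, length.out = n_win)],
      duration_s = duration_s,
      samples = split(df$vm[idx], win)
    )
  }

  if (length(keys) == 0) {
    out <- cut_bout(vm)
    if (is.null(out)) {
      warn("Series shorter than one window; no windows produced.")
      out <- tibble(window_start = numeric(), duration_s = numeric(),
                    samples = list())
    }
    return(out)
  }

  out <- vm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      res <- cut_bout(df)
      if (is.null(res))
        res <- tibble(window_start = numeric(), duration_s = numeric(),
                      samples = list())
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys[keys == "subject"],
                                                 "window_start"))))
  if (nrow(out) == 0) warn("Series shorter than one window; no windows produced.")
  out
}

#' Window Mean of the VM series
#'
#' The arithmetic mean of the VM samples in each window — the sole predictor
#' of the closed-form regression models and the score thresholded by the
#' walk/run cut-point.
#'
#' @param windows A windows tibble from [segment_windows()].
#' @return Numeric vector, one Mean (in g) per window row.
#' @export
window_mean <- function(windows) {
  if (!"samples" %in% names(windows))
    abort("`windows` must have a `samples` list-column (see `segment_windows()`).")
  unname(vapply(windows$samples, function(s) {
    if (length(s) == 0) abort("Empty window.")
    mean(s)
  }, numeric(1)))
}

#' Extract the nine summary features per window
#'
#' Computes mean, sd (denominator n-1), max, min and the 10/25/50/75/90th
#' percentiles (linear interpolation between order statistics) of the VM
#' samples in each window, appending them as columns and dropping the
#' `samples` list-column.
#'
#' @param windows A windows tibble from [segment_windows()]; every window
#'   must contain at least 2 samples.
#' @return The input tibble with the nine feature columns (see
#'   [feature_names()]) in place of `samples`.
#' @examples
#' w <- tibble::tibble(window_start = 0, duration_s = 60,
#'                     samples = list(1:100))
#' extract_features(w)$p50  # 50.5
#' @export
extract_features <- function(windows) {
  if (!"samples" %in% names(windows))
    abort("`windows` must have a `samples` list-column.")
  feats <- purrr::map(windows$samples, function(s) {
    if (length(s) < 2) abort("Windows must contain at least 2 samples.")
    qs <- quantile(s, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                   names = FALSE, type = 7)
    tibble(mean = mean(s), sd = sd(s), max = max(s), min = min(s),
           p10 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p90 = qs[5])
  }) |> purrr::list_rbind()
  dplyr::bind_cols(dplyr::select(windows, -"samples"), feats)
}

#' Fit a min-max normalizer on training features
#'
#' Records the per-feature minimum and maximum of the training rows; these
#' bounds are frozen and later applied (unchanged) to validation data so that
#' no information leaks from the validation split.
#'
#' @param data Data frame of training rows.
#' @param cols Character vector of feature columns (default the nine window
#'   features).
#' @return An object of class `minmax_normalizer` holding the bounds.
#' @export
fit_normalizer <- function(data, cols = feature_names()) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0)
    abort(paste0("Missing feature column(s): ", paste(miss, collapse = ", "), "."))
  if (nrow(data) < 1) abort("Need at least one training row.")
  structure(
    list(cols = cols,
         x_min = vapply(data[cols], min, numeric(1)),
         x_max = vapply(data[cols], max, numeric(1))),
    class = "minmax_normalizer")
}

#' Apply (or invert) a fitted min-max normalizer
#'
#' Maps each feature to `(x - x_min) / (x_max - x_min)` using the training
#' bounds. Constant training features (`x_max == x_min`) map to 0. Values
#' outside the training range are not clipped — they fall outside `[0, 1]`
#' and trigger a warning, which is the honest behaviour for validation rows
#' beyond the training support.
#'
#' @param data Data frame containing the normalizer's feature columns.
#' @param bounds A `minmax_normalizer` from [fit_normalizer()].
#' @return `data` with the feature columns replaced by their normalized
#'   values.
#' @export
apply_normalizer <- function(data, bounds) {
  if (!inherits(bounds, "minmax_normalizer"))
    abort("`bounds` must come from `fit_normalizer()`.")
  miss <- setdiff(bounds$cols, names(data))
  if (length(miss) > 0)
    abort(paste0("Missing feature column(s): ", paste(miss, collapse = ", "), "."))
  out <- data
  outside <- FALSE
  for (col in bounds$cols) {
    rng <- bounds$x_max[[col]] - bounds$x_min[[col]]
    z <- if (rng == 0) rep(0, nrow(data))
         else (data[[col]] - bounds$x_min[[col]]) / rng
    if (any(z < 0 | z > 1)) outside <- TRUE
    out[[col]] <- z
  }
  if (outside)
    warn("Some values fall outside the training range; normalized values outside [0, 1].")
  out
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(data, bounds) {
  if (!inherits(bounds, "minmax_normalizer"))
    abort("`bounds` must come from `fit_normalizer()`.")
  out <- data
  for (col in bounds$cols) {
    rng <- bounds$x_max[[col]] - bounds$x_min[[col]]
    out[[col]] <- if (rng == 0) rep(bounds$x_min[[col]], nrow(data))
                  else data[[col]] * rng + bounds$x_min[[col]]
  }
  out
}

#' Featurize a VM series in one step
#'
#' Convenience wrapper: [segment_windows()] then [extract_features()], with
#' the window Mean guaranteed present as the `mean` column.
#'
#' @inheritParams segment_windows
#' @return A feature tibble, one row per window.
#' @export
featurize <- function(vm, duration_s = 60, rate = 100) {
  extract_features(segment_windows(vm, duration_s = duration_s, rate = rate))
}
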