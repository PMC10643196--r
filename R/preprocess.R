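#' Kalman filter parameters for the local-level smoother
#'
#' Bundles the noise variances of the scalar random-walk (local-level) Kalman
#' filter applied independently to each acceleration axis. The latent state is
#' the smoothed acceleration; it evolves as a random walk with variance
#' `process_var` per step and is observed with variance `measurement_var`.
#'
#' The defaults (process variance 1e-4 g^2, measurement variance 1e-2 g^2)
#' give a mildly smoothing filter with a steady-state gain near 0.1 at 100 Hz,
#' which damps sensor noise while preserving the arm-swing oscillation.
#'
#' @param process_var Variance of the latent-state random walk per step
#'   (g^2). Must be positive.
#' @param measurement_var Observation noise variance (g^2). Must be positive.
#' @param initial_state Prior mean of the state before the first observation.
#'   `NULL` (default) uses the first observation.
#' @param initial_var Prior variance of the state. `NULL` (default) uses
#'   `measurement_var`.
#' @return An object of class `kalman_params`.
#' @examples
#' kalman_params()
#' kalman_params(process_var = 1e-3)
#' @export
kalman_params <- function(process_var = 1e-4, measurement_var = 1e-2,
                          initial_state = NULL, initial_var = NULL) {
  if (!is.numeric(process_var) || length(process_var) != 1 || process_var <= 0)
    abort("`process_var` must be a single positive number.")
  if (!is.numeric(measurement_var) || length(measurement_var) != 1 ||
      measurement_var <= 0)
    abort("`measurement_var` must be a single positive number.")
  if (!is.null(initial_var) && initial_var < 0)
    abort("`initial_var` must be non-negative.")
  structure(
    list(process_var = process_var, measurement_var = measurement_var,
         initial_state = initial_state, initial_var = initial_var),
    class = "kalman_params")
}

#' Smooth one acceleration axis with a local-level Kalman filter
#'
#' Runs the scalar predict/update recursion of a random-walk state-space model
#' over a single axis. The filter state is initialised at the first
#' observation (unless overridden in `params`), so there is no start-up bias
#' for signals with a non-zero baseline such as the gravity component.
#'
#' The Kalman gain depends only on the variances, not on the data, so the gain
#' sequence is precomputed to convergence and the steady-state tail is run
#' through a fast recursive filter; the result is the exact recursion up to
#' the gain convergence tolerance (1e-15).
#'
#' @param x Numeric vector, one acceleration axis in g. Must be non-empty and
#'   finite.
#' @param params A [kalman_params()] object.
#' @return Numeric vector of the same length: the filtered (smoothed) axis.
#' @examples
#' x <- sin(seq(0, 10, by = 0.01)) + rnorm(1001, sd = 0.1)
#' s <- kalman_smooth(x, kalman_params())
#' var(s) < var(x)
#' @export
kalman_smooth <- function(x, params = kalman_params()) {
  if (!inherits(params, "kalman_params")) abort("`params` must be a `kalman_params` object.")
  if (length(x) == 0) abort("`x` must be non-empty.")
  assert_finite(x, "x")
  q <- params$process_var
  r <- params$measurement_var
  s0 <- if (is.null(params$initial_state)) x[1] else params$initial_state
  p0 <- if (is.null(params$initial_var)) r else params$initial_var
  n <- length(x)

  # gain sequence: data-independent, geometric convergence to steady state
  gains <- numeric(n)
  p <- p0
  m <- 0L
  k_prev <- -1
  for (i in seq_len(n)) {
    pp <- p + q
    k <- pp / (pp + r)
    gains[i] <- k
    p <- (1 - k) * pp
    m <- i
    if (abs(k - k_prev) < 1e-15) break
    k_prev <- k
  }

  out <- numeric(n)
  s <- s0
  for (i in seq_len(m)) {
    s <- s + gains[i] * (x[i] - s)
    out[i] <- s
  }
  if (n > m) {
    k <- gains[m]
    out[(m + 1):n] <- stats::filter(k * x[(m + 1):n], 1 - k,
                                    method = "recursive", init = s)
  }
  out
}

#' Remove the gravity trend with a trailing rolling mean
#'
#' Subtracts from every sample the mean of the trailing `trend_window_s`
#' seconds (inclusive of the current sample). During the first
#' `trend_window_s` seconds the mean is taken over the expanding head of the
#' series, so the output has the same length as the input and no samples are
#' dropped. A constant (gravity-only) signal maps to exactly zero.
#'
#' @param x Numeric vector, one smoothed acceleration axis in g.
#' @param rate Sampling rate in Hz.
#' @param trend_window_s Trailing window length in seconds (default 5).
#' @return Numeric vector of the same length: the detrended axis.
#' @examples
#' remove_gravity_trend(rep(1, 1000), rate = 100)  # all zeros
#' @export
remove_gravity_trend <- function(x, rate, trend_window_s = 5) {
  if (length(x) == 0) abort("`x` must be non-empty.")
  if (!is.numeric(rate) || rate <= 0) abort("`rate` must be positive.")
  if (!is.numeric(trend_window_s) || trend_window_s <= 0)
    abort("`trend_window_s` must be positive.")
  n <- length(x)
  w <- floor(trend_window_s * rate) + 1  # inclusive of the current sample
  cs <- cumsum(x)
  idx <- seq_len(n)
  trail <- ifelse(idx >= w, (cs - c(rep(0, w), head(cs, n - w))) / w, cs / idx)
  x - trail
}

#' Vector magnitude of tri-axial acceleration
#'
#' Combines the three axes into the composite acceleration
#' `VM = sqrt(ax^2 + ay^2 + az^2)`, the working signal of the whole pipeline.
#'
#' @param ax,ay,az Equal-length numeric vectors (g).
#' @return Non-negative numeric vector of the same length.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    abort("`ax`, `ay`, `az` must have equal lengths.")
  assert_finite(ax, "ax"); assert_finite(ay, "ay"); assert_finite(az, "az")
  sqrt(ax^2 + ay^2 + az^2)
}

label_cols <- function(stream) {
  intersect(c("subject", "speed_kmh", "gait"), names(stream))
}

validate_stream <- function(stream, rate = NULL) {
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(stream))
  if (length(miss) > 0)
    abort(paste0("Accelerometer stream is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  if (nrow(stream) == 0) abort("Accelerometer stream is empty.")
  if (is.unsorted(stream$t, strictly = TRUE))
    abort("`t` must be strictly increasing.")
  for (col in c("ax", "ay", "az")) assert_finite(stream[[col]], col)
  if (!is.null(rate) && nrow(stream) > 1) {
    dt <- diff(stream$t)
    bad <- which(abs(dt - 1 / rate) > 0.1 / rate)
    if (length(bad) > 0)
      abort(sprintf(
        "Sample interval deviates more than 10%% from 1/%g s at t = %g.",
        rate, stream$t[bad[1]]))
  }
  invisible(stream)
}

#' Preprocess a raw acceleration stream into a vector-magnitude series
#'
#' Applies the three preprocessing steps in order — Kalman smoothing and
#' gravity detrending per axis, then the vector magnitude — turning a raw
#' tri-axial stream into the non-negative VM series used for windowing.
#' Bout labels (`subject`, `speed_kmh`, `gait`), when present, are carried
#' through unchanged.
#'
#' @param stream Data frame with columns `t` (seconds, strictly increasing,
#'   nominal `rate` Hz with at most 10% jitter), `ax`, `ay`, `az` (g), and
#'   optionally `subject`, `speed_kmh`, `gait`.
#' @param params A [kalman_params()] object.
#' @param trend_window_s Detrending window in seconds (default 5).
#' @param rate Sampling rate in Hz (default 100).
#' @return A tibble with columns `t`, `vm` and any label columns present in
#'   the input.
#' @examples
#' stream <- tibble::tibble(t = seq(0, 1, by = 0.01),
#'                          ax = 0, ay = 0, az = 1)
#' vm <- preprocess_stream(stream)
#' max(tail(vm$vm, 10)) < 1e-8  # gravity removed
#' @export
preprocess_stream <- function(stream, params = kalman_params(),
                              trend_window_s = 5, rate = 100) {
  validate_stream(stream, rate = rate)
  axes <- lapply(stream[c("ax", "ay", "az")], function(a) {
    remove_gravity_trend(kalman_smooth(a, params), rate = rate,
                         trend_window_s = trend_window_s)
  })
  out <- tibble(t = stream$t,
                vm = vector_magnitude(axes$ax, axes$ay, axes$az))
  for (col in label_cols(stream)) out[[col]] <- stream[[col]]
  out
}

#' Raw vector-magnitude series (no smoothing or detrending)
#'
#' Computes VM directly from the unfiltered axes. This is the feature source
#' used for the neural-network summary statistics, which are taken from the
#' original signal rather than the detrended one.
#'
#' @inheritParams preprocess_stream
#' @return A tibble with columns `t`, `vm` and any label columns.
#' @export
raw_vm_stream <- function(stream) {
  validate_stream(stream)
  out <- tibble(t = stream$t,
                vm = vector_magnitude(stream$ax, stream$ay, stream$az))
  for (col in label_cols(stream)) out[[col]] <- stream[[col]]
  out
}
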