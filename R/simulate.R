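#' Treadmill protocol specification
#'
#' The experimental protocol emulated by the simulator: eight 4-minute
#' treadmill bouts at 2-9 km/h sampled at 100 Hz, with speeds up to 6 km/h
#' walked and speeds of 7 km/h and above run.
#'
#' @param speeds_kmh Bout speeds in km/h, positive and sorted (default 2:9).
#' @param bout_s Bout duration in seconds (default 240).
#' @param rate Sampling rate in Hz (default 100).
#' @param run_threshold_kmh Speeds at or above this are run, below walked
#'   (default 7).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(speeds_kmh = 2:9, bout_s = 240, rate = 100,
                          run_threshold_kmh = 7) {
  if (any(speeds_kmh <= 0) || is.unsorted(speeds_kmh))
    abort("`speeds_kmh` must be positive and sorted.")
  if (bout_s <= 0 || rate <= 0) abort("`bout_s` and `rate` must be positive.")
  structure(list(speeds_kmh = speeds_kmh, bout_s = bout_s, rate = rate,
                 run_threshold_kmh = run_threshold_kmh),
            class = "protocol_spec")
}

#' Gait label implied by treadmill speed
#'
#' @param speed_kmh Numeric vector of speeds.
#' @param protocol A [protocol_spec()].
#' @return Character vector of `"walk"` / `"run"`.
#' @export
gait_from_speed <- function(speed_kmh, protocol = protocol_spec()) {
  ifelse(speed_kmh >= protocol$run_threshold_kmh, "run", "walk")
}

#' Simulation configuration
#'
#' Study-level settings of the synthetic cohort: 100 subjects split 70/30
#' into modeling and validation groups by subject (never by window), with
#' between-subject variability in both the metabolic level and the arm-swing
#' amplitude.
#'
#' Noise levels: each axis carries Gaussian sensor noise (sd 0.02 g); the
#' per-window measured METs carry measurement noise (sd 0.4 METs) around the
#' subject's true value; subjects differ by a METs offset (sd 0.3 METs) and
#' a multiplicative arm-swing amplitude factor drawn uniformly from
#' `amp_scale_range`. The amplitude range is deliberately narrow so that the
#' walking and running window-Mean distributions stay separated across the
#' whole cohort, mirroring the perfectly separable Mean observed on the
#' treadmill protocol.
#'
#' @param n_subjects Number of subjects (default 100).
#' @param n_modeling Modeling-group size (default 70); the remaining
#'   subjects form the validation group.
#' @param seed Master seed; every other random draw is derived from it.
#' @param axis_noise_sd Per-axis sensor noise sd in g (default 0.02).
#' @param mets_noise_sd Per-window METs measurement noise sd (default 0.4).
#' @param mets_offset_sd Between-subject METs offset sd (default 0.3).
#' @param amp_scale_range Range of the subject amplitude factor (default
#'   `c(0.85, 1.2)`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 100, n_modeling = 70, seed = 42,
                       axis_noise_sd = 0.02, mets_noise_sd = 0.4,
                       mets_offset_sd = 0.3, amp_scale_range = c(0.85, 1.2)) {
  if (n_modeling >= n_subjects)
    abort("`n_modeling` must be smaller than `n_subjects`.")
  if (any(c(axis_noise_sd, mets_noise_sd, mets_offset_sd) < 0))
    abort("Noise sds must be non-negative.")
  if (length(amp_scale_range) != 2 || amp_scale_range[1] <= 0 ||
      diff(amp_scale_range) < 0)
    abort("`amp_scale_range` must be an increasing positive pair.")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_modeling = as.integer(n_modeling),
                 seed = as.integer(seed),
                 axis_noise_sd = axis_noise_sd,
                 mets_noise_sd = mets_noise_sd,
                 mets_offset_sd = mets_offset_sd,
                 amp_scale_range = amp_scale_range),
            class = "sim_config")
}

#' Draw the subject cohort
#'
#' Generates the per-subject random effects (METs offset, amplitude factor)
#' and a derived per-subject seed, all deterministically from the master
#' seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `subject`, `mets_offset`, `amp_scale`,
#'   `seed`.
#' @export
subject_profiles <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    tibble(
      subject = sprintf("S%03d", seq_len(config$n_subjects)),
      mets_offset = rnorm(config$n_subjects, 0, config$mets_offset_sd),
      amp_scale = runif(config$n_subjects, config$amp_scale_range[1],
                        config$amp_scale_range[2]),
      seed = sample.int(.Machine$integer.max - 1L, config$n_subjects)
    )
  })
}

#' Ground-truth METs for a treadmill bout
#'
#' The simulator's energy-expenditure oracle, standing in for indirect
#' calorimetry: ACSM-style walking and running oxygen-cost curves converted
#' to METs. With speed `v` in m/min, walking costs `(0.1 v + 3.5)/3.5` METs
#' and running `(0.2 v + 3.5)/3.5` METs, plus the subject's METs offset.
#' Within each gait the curve is strictly increasing in speed.
#'
#' @param speed_kmh Numeric vector of speeds (km/h, positive).
#' @param gait `"walk"` or `"run"` (recycled).
#' @param mets_offset Subject-level offset in METs (default 0).
#' @return Numeric vector of METs.
#' @examples
#' true_mets(6, "walk")  # ~3.857
#' true_mets(9, "run")   # ~10.571
#' @export
true_mets <- function(speed_kmh, gait, mets_offset = 0) {
  if (any(speed_kmh <= 0)) abort("`speed_kmh` must be positive.")
  v <- speed_kmh * 1000 / 60  # m/min
  base <- ifelse(gait == "run", (0.2 * v + 3.5) / 3.5, (0.1 * v + 3.5) / 3.5)
  base + mets_offset
}

# Arm-swing sinusoid parameters: step frequency and per-axis amplitude as
# declared functions of treadmill speed.
step_freq_hz <- function(speed_kmh) 0.8 + 0.25 * speed_kmh
swing_amp_g <- function(speed_kmh, gait, amp_scale) {
  amp_scale * ifelse(gait == "run", 0.05, 0.03) * speed_kmh
}

#' Simulate one subject's accelerometer stream
#'
#' Generates the raw tri-axial wrist stream for the full protocol: each axis
#' is a constant gravity projection (a random unit wrist orientation held
#' for the whole protocol) plus an arm-swing sinusoid at the speed-dependent
#' step frequency
#' with a speed- and gait-dependent amplitude and axis-specific phase, plus
#' Gaussian sensor noise. Per-window measured METs are the ground-truth
#' curve plus measurement noise. Everything is drawn from the subject's
#' derived seed, so streams are reproducible.
#'
#' @param profile One row of [subject_profiles()] (data frame or list with
#'   `subject`, `mets_offset`, `amp_scale`, `seed`).
#' @param protocol A [protocol_spec()].
#' @param config A [sim_config()].
#' @param duration_s Window length used for the measured-METs grid
#'   (default 60).
#' @return A list with `stream` (tibble `t`, `ax`, `ay`, `az`, `subject`,
#'   `speed_kmh`, `gait`) and `mets` (tibble `subject`, `speed_kmh`, `gait`,
#'   `window_start`, `measured_mets`).
#' @export
simulate_stream <- function(profile, protocol = protocol_spec(),
                            config = sim_config(), duration_s = 60) {
  if (is.data.frame(profile)) profile <- as.list(profile[1, ])
  n_bout <- length(protocol$speeds_kmh)
  n_per <- as.integer(round(protocol$bout_s * protocol$rate))
  n_win <- protocol$bout_s %/% duration_s

  withr::with_seed(profile$seed, {
    g_dir <- rnorm(3)
    g_dir <- g_dir / sqrt(sum(g_dir^2))  # constant wrist pose for the subject
    bouts <- purrr::imap(protocol$speeds_kmh, function(v, i) {
      gait <- gait_from_speed(v, protocol)
      t0 <- (i - 1) * protocol$bout_s
      t <- t0 + (seq_len(n_per) - 1) / protocol$rate
      f <- step_freq_hz(v)
      A <- swing_amp_g(v, gait, profile$amp_scale)
      # random global phase, axes offset by 120 degrees: the sum of the three
      # squared sinusoids is then exactly 3/2, so the VM envelope is constant
      # and the window Mean depends on amplitude, not on phase luck
      phases <- runif(1, 0, 2 * pi) + 2 * pi * (0:2) / 3
      ax_l <- lapply(1:3, function(k) {
        g_dir[k] + A * sin(2 * pi * f * t + phases[k]) +
          rnorm(n_per, 0, config$axis_noise_sd)
      })
      stream <- tibble(t = t, ax = ax_l[[1]], ay = ax_l[[2]], az = ax_l[[3]],
                       subject = profile$subject, speed_kmh = v, gait = gait)
      mets <- tibble(subject = profile$subject, speed_kmh = v, gait = gait,
                     window_start = t0 + duration_s * (seq_len(n_win) - 1),
                     measured_mets = true_mets(v, gait, profile$mets_offset) +
                       rnorm(n_win, 0, config$mets_noise_sd))
      list(stream = stream, mets = mets)
    })
    list(stream = purrr::list_rbind(purrr::map(bouts, "stream")),
         mets = purrr::list_rbind(purrr::map(bouts, "mets")))
  })
}

#' Generate the full synthetic feature dataset
#'
#' Runs the entire front end of the pipeline for every simulated subject:
#' raw stream, Kalman smoothing + detrending + VM, windowing, and feature
#' extraction — producing modeling- and validation-group feature tables
#' split by subject. Each row is one window with:
#' \itemize{
#'   \item the nine network features ([feature_names()]) computed from the
#'     raw VM,
#'   \item `mean_vm`, the window Mean of the preprocessed (smoothed,
#'     detrended) VM used by the regressions and the walk/run cut-point,
#'   \item `measured_mets`, the noisy ground-truth METs for the window.
#' }
#'
#' @param config A [sim_config()].
#' @param protocol A [protocol_spec()].
#' @param duration_s Window length in seconds (default 60).
#' @param kalman A [kalman_params()].
#' @param trend_window_s Detrending window in seconds (default 5).
#' @return A list of class `ee_dataset`: `$modeling` and `$validation`
#'   feature tibbles, `$profiles`, `$config`, `$protocol`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(sim_config(n_subjects = 4, n_modeling = 3))
#' nrow(ds$modeling)  # 3 subjects x 8 speeds x 4 windows = 96
#' }
#' @export
generate_dataset <- function(config = sim_config(),
                             protocol = protocol_spec(), duration_s = 60,
                             kalman = kalman_params(), trend_window_s = 5) {
  profiles <- subject_profiles(config)
  feats <- purrr::pmap(profiles, function(subject, mets_offset, amp_scale, seed) {
    prof <- list(subject = subject, mets_offset = mets_offset,
                 amp_scale = amp_scale, seed = seed)
    sim <- simulate_stream(prof, protocol, config, duration_s)
    raw <- featurize(raw_vm_stream(sim$stream), duration_s, protocol$rate)
    pre <- preprocess_stream(sim$stream, kalman, trend_window_s,
                             protocol$rate)
    pre_win <- segment_windows(pre, duration_s, protocol$rate)
    pre_mean <- dplyr::select(pre_win, dplyr::all_of(c(label_cols(pre_win),
                                                       "window_start")))
    pre_mean$mean_vm <- window_mean(pre_win)
    raw |>
      dplyr::left_join(pre_mean,
                       by = c(label_cols(raw), "window_start")) |>
      dplyr::left_join(sim$mets, by = c(label_cols(raw), "window_start"))
  }) |> purrr::list_rbind()

  modeling_ids <- withr::with_seed(
    config$seed + 1L, sample(profiles$subject, config$n_modeling))
  structure(
    list(modeling = dplyr::filter(feats, .data$subject %in% modeling_ids),
         validation = dplyr::filter(feats, !.data$subject %in% modeling_ids),
         profiles = profiles, config = config, protocol = protocol),
    class = "ee_dataset")
}

#' @export
print.ee_dataset <- function(x, ...) {
  cat(sprintf(
    "<ee_dataset> %d modeling + %d validation windows (%d + %d subjects)\n",
    nrow(x$modeling), nrow(x$validation), x$config$n_modeling,
    x$config$n_subjects - x$config$n_modeling))
  invisible(x)
}

#' Generate (Mean, METs) calibration pairs from a reference model
#'
#' Draws window Means uniformly over `mean_range` and METs from the given
#' closed-form model plus Gaussian noise — the standard instrument for
#' coefficient-recovery checks against the published equations.
#'
#' @param model An [ee_model()] (default the linear reference model).
#' @param n Number of pairs (>= 10).
#' @param noise_sd METs noise sd (default the linear reference SEE, 0.96).
#' @param mean_range Range of Means (default `c(0.05, 0.9)`); must stay
#'   positive for a logarithmic model.
#' @param seed Seed.
#' @return A tibble with columns `mean`, `mets`.
#' @export
generate_calibration_pairs <- function(model = ee_reference_model("linear"),
                                       n = 560, noise_sd = 0.96,
                                       mean_range = c(0.05, 0.9), seed = 1) {
  if (n < 10) abort("`n` must be at least 10.")
  if (model$kind == "logarithmic" && mean_range[1] <= 0)
    abort("`mean_range` must be strictly positive for a logarithmic model.")
  withr::with_seed(seed, {
    m <- runif(n, mean_range[1], mean_range[2])
    tibble(mean = m, mets = predict(model, m) + rnorm(n, 0, noise_sd))
  })
}
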