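# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A desk-scale cohort: 6 subjects, 4 modeling / 2 validation.
small_dataset <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_dataset(
      sim_config(n_subjects = 6, n_modeling = 4, seed = 11))
  }
  .fixture_cache$small
}

# The default study-scale cohort (100 subjects, 70/30, master seed 42);
# used by the end-to-end acceptance checks.
default_dataset <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- generate_dataset()
  }
  .fixture_cache$default
}

# A single short two-bout stream with labels, for windowing tests.
two_bout_stream <- function(bout_s = 130, rate = 100) {
  n <- bout_s * rate
  mk <- function(speed, gait, offset) {
    tibble::tibble(
      t = offset + (seq_len(n) - 1) / rate,
      ax = 0.1 * sin(2 * pi * 2 * (seq_len(n) - 1) / rate),
      ay = 0.05 * cos(2 * pi * 2 * (seq_len(n) - 1) / rate),
      az = 1,
      subject = "S1", speed_kmh = speed,
      gait = gait)
  }
  dplyr::bind_rows(mk(6, "walk", 0), mk(7, "run", bout_s))
}
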