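vm_series <- function(n, rate = 100, value = abs(sin(seq_len(n))))
  tibble::tibble(t = (seq_len(n) - 1) / rate, vm = value)

test_that("windows are cut per bout with the trailing partial discarded", {
  expect_equal(nrow(segment_windows(vm_series(24000), 60)), 4)
  expect_equal(nrow(segment_windows(vm_series(24000), 10)), 24)
  w <- segment_windows(vm_series(25000), 60)  # 250 s -> 4 windows, 10 s dropped
  expect_equal(nrow(w), 4)
  expect_equal(sum(lengths(w$samples)), 24000)
})

test_that("windows never span two bouts", {
  vm <- raw_vm_stream(two_bout_stream(bout_s = 130))  # 130 s per bout
  w <- segment_windows(vm, 60)
  # each 130 s bout gives 2 whole windows; 10 s at each bout tail dropped
  expect_equal(nrow(w), 4)
  expect_equal(w$speed_kmh, c(6, 6, 7, 7))
  expect_true(all(lengths(w$samples) == 6000))
})

test_that("a series shorter than one window warns and yields no windows", {
  expect_warning(w <- segment_windows(vm_series(500), 60), "shorter")
  expect_equal(nrow(w), 0)
})

test_that("window Mean is the arithmetic mean, incl. the rectified sinusoid", {
  w <- tibble::tibble(window_start = 0, duration_s = 60,
                      samples = list(rep(0.3, 100)))
  expect_equal(window_mean(w), 0.3)
  w2 <- tibble::tibble(window_start = 0, duration_s = 60,
                       samples = list(c(0, 0.2, 0.4)))
  expect_equal(window_mean(w2), 0.2)
  A <- 0.4
  dense <- abs(A * sin(seq(0, 200 * pi, length.out = 2e5)))
  w3 <- tibble::tibble(window_start = 0, duration_s = 60, samples = list(dense))
  expect_equal(window_mean(w3), 2 * A / pi, tolerance = 1e-3)
})

test_that("feature extraction handles constants and interpolated percentiles", {
  const <- extract_features(tibble::tibble(window_start = 0, duration_s = 60,
                                           samples = list(rep(0.5, 50))))
  for (f in feature_names())
    expect_equal(const[[f]], if (f == "sd") 0 else 0.5)
  seq100 <- extract_features(tibble::tibble(window_start = 0, duration_s = 60,
                                            samples = list(1:100)))
  expect_equal(seq100$p50, 50.5)
  expect_equal(seq100$sd, sd(1:100))  # n-1 denominator
})

test_that("features agree with the sort-based percentile oracle", {
  set.seed(31)
  for (i in 1:20) {
    x <- runif(50)
    f <- extract_features(tibble::tibble(window_start = 0, duration_s = 60,
                                         samples = list(x)))
    for (p in c(10, 25, 50, 75, 90))
      expect_equal(f[[paste0("p", p)]], bf_percentile(x, p / 100),
                   tolerance = 1e-12)
    # ordering invariant
    vals <- unlist(f[c("min", "p10", "p25", "p50", "p75", "p90", "max")])
    expect_true(all(diff(vals) >= 0))
    expect_true(f$min <= f$mean && f$mean <= f$max)
  }
})

test_that("normalizer bounds come from the training rows", {
  d1 <- tibble::tibble(a = 3, b = -1)
  b1 <- fit_normalizer(d1, c("a", "b"))
  expect_equal(unname(b1$x_min), c(3, -1))
  expect_equal(unname(b1$x_max), c(3, -1))
  d2 <- tibble::tibble(a = c(2, 4, 6))
  expect_equal(unname(fit_normalizer(d2, "a")$x_max), 6)
})

test_that("normalization maps endpoints and midpoints as defined", {
  train <- tibble::tibble(x = c(2, 6))
  b <- fit_normalizer(train, "x")
  expect_equal(apply_normalizer(tibble::tibble(x = c(2, 4, 6)), b)$x,
               c(0, 0.5, 1))
  # constant feature maps to 0
  bc <- fit_normalizer(tibble::tibble(x = c(5, 5)), "x")
  expect_equal(apply_normalizer(tibble::tibble(x = 5), bc)$x, 0)
  # out-of-range values are not clipped and warn
  expect_warning(out <- apply_normalizer(tibble::tibble(x = 8), b), "outside")
  expect_equal(out$x, 1.5)
  expect_error(apply_normalizer(tibble::tibble(y = 1), b), "Missing feature")
})

test_that("normalized training data lies in [0,1] and inverts exactly", {
  set.seed(41)
  train <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(45), 5)),
                                      feature_names()))
  b <- fit_normalizer(train)
  z <- apply_normalizer(train, b)
  expect_true(all(as.matrix(z[feature_names()]) >= 0 &
                  as.matrix(z[feature_names()]) <= 1))
  back <- invert_normalizer(z, b)
  expect_equal(as.data.frame(back), as.data.frame(train), tolerance = 1e-12)
})
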