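test_that("RMSE and Bias reproduce hand-computed values", {
  expect_equal(rmse(c(3, 4), c(4, 4)), sqrt(0.5))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(bias(6, 5, "relative"), 0.2)
  expect_equal(bias(6, 5, "absolute"), 1)
  expect_equal(bias(c(4, 6), c(5, 5), "relative"), 0)
  expect_equal(bias(c(4, 6), c(5, 5), "absolute"), 0)
  expect_error(bias(1, 0, "relative"), "!= 0")
  expect_error(rmse(1:3, 1:2), "equal lengths")
})

test_that("metrics match the brute-force recomputation on random instances", {
  withr::with_seed(43, {
    for (i in 1:50) {
      n <- sample(3:40, 1)
      p <- rnorm(n, 5); m <- runif(n, 2, 11)
      expect_equal(rmse(p, m), bf_rmse(p, m), tolerance = 1e-12)
      expect_equal(bias(p, m, "relative"), bf_bias_rel(p, m), tolerance = 1e-12)
      expect_equal(bias(p, m, "absolute"), bf_bias_abs(p, m), tolerance = 1e-12)
      ba <- bland_altman(p, m)
      expect_equal(c(ba$loa_low, ba$loa_high), bf_loa(p, m), tolerance = 1e-12)
      expect_gte(rmse(p, m), abs(bf_bias_abs(p, m)))  # Jensen
    }
  })
})

test_that("Bland-Altman handles degenerate and textbook cases", {
  ba0 <- bland_altman(c(2, 3, 4) + 0.5, c(2, 3, 4))
  expect_equal(ba0$loa_low, ba0$mean_diff)
  expect_equal(ba0$loa_high, ba0$mean_diff)
  expect_equal(ba0$n_outside, 0)

  ba <- bland_altman(c(4, 5, 6), c(5, 5, 5))  # d = -1, 0, 1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$n_outside, 0)
  expect_error(bland_altman(1:2, 2:3), "3 pairs")
})

test_that("~5% of Gaussian differences fall outside the 95% limits", {
  withr::with_seed(47, {
    m <- runif(10000, 2, 10)
    p <- m + rnorm(10000)
  })
  ba <- bland_altman(p, m)
  expect_gt(ba$frac_outside, 0.035)
  expect_lt(ba$frac_outside, 0.065)
})

test_that("a perfect model evaluates to all-zero errors", {
  ds <- small_dataset()
  d <- ds$validation
  d$predicted <- d$measured_mets
  rep <- evaluate_predictions(d)
  expect_equal(rep$overall$rmse, 0)
  expect_equal(rep$overall$bias, 0)
  expect_true(all(rep$per_speed$rmse == 0))
  expect_true(all(rep$per_gait$bias == 0))
})

test_that("per-speed squared RMSEs pool exactly to the overall RMSE", {
  ds <- small_dataset()
  d <- ds$validation
  d$predicted <- predict(ee_reference_model("linear"), d$mean_vm)
  rep <- evaluate_predictions(d)
  pooled <- sqrt(sum(rep$per_speed$rmse^2 * rep$per_speed$n) /
                   sum(rep$per_speed$n))
  expect_equal(pooled, rep$overall$rmse, tolerance = 1e-12)
  expect_equal(sum(rep$per_speed$n), rep$overall$n)  # rows partition
  expect_equal(sum(rep$per_gait$n), rep$overall$n)
})

test_that("reports order speeds, label the bias mode, and validate keys", {
  ds <- small_dataset()
  d <- ds$validation
  d$predicted <- d$measured_mets + 0.5
  rep <- evaluate_predictions(d, bias_mode = "absolute")
  expect_equal(rep$bias_mode, "absolute")
  expect_equal(rep$per_speed$speed_kmh, sort(unique(d$speed_kmh)))
  expect_equal(rep$overall$bias, 0.5, tolerance = 1e-12)
  expect_error(evaluate_predictions(d, group_keys = "subject"),
               "Unknown group key")
})

test_that("evaluate_model works for every predictor class", {
  ds <- small_dataset()
  reg <- evaluate_model(ee_reference_model("linear"), ds$validation)
  expect_s3_class(reg, "eval_report")
  fit <- fit_ee_regression(
    dplyr::rename(ds$modeling, mets = "measured_mets"), "linear",
    mean_col = "mean_vm")
  expect_s3_class(evaluate_model(fit, ds$validation), "eval_report")
  ann <- train_ann(ds$modeling,
                   config = ann_config(hidden_n = 3, max_iter = 300))
  rep <- evaluate_model(ann, ds$validation)
  expect_true(rep$overall$rmse < 2)  # loose sanity: model has learned something
})

test_that("evaluation plots build without error", {
  ds <- small_dataset()
  d <- ds$validation
  d$predicted <- d$measured_mets + rnorm(nrow(d), 0, 0.3)
  rep <- evaluate_predictions(d)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep$bland_altman), "ggplot")
  roc <- roc_analysis(ds$modeling, mean_col = "mean_vm")
  expect_s3_class(autoplot(roc), "ggplot")
  expect_s3_class(plot_mean_scatter(ds$modeling, cutoff = youden_cutoff(roc)),
                  "ggplot")
})
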