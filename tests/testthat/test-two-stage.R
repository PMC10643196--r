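test_that("ROC on separated classes gives AUC 1; uninformative scores ~0.5", {
  d <- tibble::tibble(mean = c(0.1, 0.2, 0.3, 0.4),
                      gait = c("walk", "walk", "run", "run"))
  expect_equal(roc_analysis(d)$auc, 1)
  withr::with_seed(23, {
    big <- tibble::tibble(mean = runif(4000),
                          gait = sample(c("walk", "run"), 4000, replace = TRUE))
  })
  expect_equal(roc_analysis(big)$auc, 0.5, tolerance = 0.03)
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise oracle", {
  withr::with_seed(29, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      means <- round(runif(n), sample(c(1, 2, 6), 1))  # rounding induces ties
      labels <- sample(c("walk", "run"), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c("walk", "run")
      got <- roc_analysis(means = means, labels = labels)$auc
      expect_equal(got, bf_auc(means, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on random data", {
  withr::with_seed(37, {
    means <- c(rnorm(60, 0.15, 0.05), rnorm(40, 0.3, 0.05))
    labels <- rep(c("walk", "run"), c(60, 40))
  })
  ours <- roc_analysis(means = means, labels = labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = means, levels = c("walk", "run"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("single-class input is rejected", {
  expect_error(roc_analysis(means = 1:3, labels = rep("walk", 3)),
               "Both classes")
})

test_that("the Youden cutoff lands in the separating gap when separable", {
  d <- tibble::tibble(mean = c(0.1, 0.2, 0.3, 0.4),
                      gait = c("walk", "walk", "run", "run"))
  cut <- youden_cutoff(roc_analysis(d))
  expect_equal(cut$threshold, 0.25)
  expect_equal(cut$youden_j, 1)
  expect_equal(classify_gait(d$mean, cut), d$gait)  # 100% on training data
})

test_that("overlapping classes give the enumerated Youden maximum", {
  d <- tibble::tibble(mean = c(0.1, 0.3, 0.2, 0.4),
                      gait = c("walk", "walk", "run", "run"))
  cut <- youden_cutoff(roc_analysis(d))
  expect_equal(cut$youden_j, 0.5)
  expect_gt(cut$threshold, 0.3)
  expect_lt(cut$threshold, 0.4)
})

test_that("classification uses a strict threshold with boundary -> walk", {
  cut <- structure(list(threshold = 0.25, youden_j = 1, auc = 1,
                        positive = "run"), class = "cutoff_model")
  expect_equal(classify_gait(0.25 + 1e-9, cut), "run")
  expect_equal(classify_gait(0.25, cut), "walk")
  expect_equal(classify_gait(0, cut), "walk")
})

test_that("separable distributions stay perfectly classified out of sample", {
  ds <- small_dataset()
  roc <- roc_analysis(ds$modeling, mean_col = "mean_vm")
  expect_equal(roc$auc, 1)
  cut <- youden_cutoff(roc)
  expect_equal(classify_gait(ds$modeling$mean_vm, cut), ds$modeling$gait)
  expect_equal(classify_gait(ds$validation$mean_vm, cut), ds$validation$gait)
})

test_that("the two-stage model trains, dispatches exactly, and is deterministic", {
  ds <- small_dataset()
  cfg_w <- ann_config(hidden_n = 4, weight_decay = 0.8, max_iter = 400)
  cfg_r <- ann_config(hidden_n = 3, weight_decay = 0.7, max_iter = 400)
  m1 <- train_two_stage(ds$modeling, cfg_w, cfg_r)
  m2 <- train_two_stage(ds$modeling, cfg_w, cfg_r)
  expect_identical(m1$walk_model$W1, m2$walk_model$W1)
  expect_equal(m1$cutoff$auc, 1)

  pred <- predict(m1, ds$validation)
  expect_true(all(is.finite(pred)))
  expect_true(all(pred > 0.5 & pred < 20))
  # piecewise contract: walk windows equal the walk sub-model's predictions
  walk_rows <- ds$validation[ds$validation$gait == "walk", ]
  expect_identical(pred[ds$validation$gait == "walk"],
                   predict(m1$walk_model, walk_rows))
  run_rows <- ds$validation[ds$validation$gait == "run", ]
  expect_identical(pred[ds$validation$gait == "run"],
                   predict(m1$run_model, run_rows))
})

test_that("a constant-METs walk stratum is predicted as that constant", {
  ds <- small_dataset()
  d <- ds$modeling
  d$measured_mets[d$gait == "walk"] <- 3
  m <- train_two_stage(d,
                       ann_config(hidden_n = 3, weight_decay = 0, max_iter = 1500),
                       ann_config(hidden_n = 3, weight_decay = 0, max_iter = 300))
  walk_pred <- predict(m, d[d$gait == "walk", ])
  expect_lt(max(abs(walk_pred - 3)), 0.05)
})

test_that("a missing gait stratum is a training error", {
  ds <- small_dataset()
  expect_error(train_two_stage(ds$modeling[ds$modeling$gait == "walk", ]),
               "strata")
})
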