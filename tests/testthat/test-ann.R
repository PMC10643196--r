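toy_data <- function(n = 200, seed = 1, noise_sd = 0) {
  withr::with_seed(seed, {
    d <- tibble::as_tibble(setNames(
      as.data.frame(matrix(runif(n * 9), n)), feature_names()))
    d$measured_mets <- rowSums(d[feature_names()]) + rnorm(n, 0, noise_sd)
    d
  })
}

test_that("a constant target is fit to machine-level accuracy", {
  d <- toy_data(60)
  d$measured_mets <- 4.2
  m <- train_ann(d, config = ann_config(hidden_n = 4, weight_decay = 0,
                                        max_iter = 2000))
  expect_lt(sqrt(mean((predict(m, d) - 4.2)^2)), 1e-3)
})

test_that("a noiseless linear target is learned within 2000 iterations", {
  d <- toy_data(200)
  m <- train_ann(d, config = ann_config(hidden_n = 8, weight_decay = 0))
  expect_lt(sqrt(mean((predict(m, d) - d$measured_mets)^2)), 0.05)
})

test_that("training is bit-identical for identical data, config and seed", {
  d <- toy_data(50, noise_sd = 0.3)
  cfg <- ann_config(hidden_n = 3, weight_decay = 0.2, max_iter = 200, seed = 7)
  a <- train_ann(d, config = cfg)
  b <- train_ann(d, config = cfg)
  expect_identical(a$W1, b$W1)
  expect_identical(a$w2, b$w2)
  expect_identical(predict(a, d), predict(b, d))
})

test_that("the loss trace never increases", {
  d <- toy_data(80, noise_sd = 0.5)
  m <- train_ann(d, config = ann_config(hidden_n = 6, weight_decay = 0.1,
                                        max_iter = 500))
  expect_true(all(diff(m$loss_trace) <= 0))
})

test_that("the forward pass matches hand-computed sigmoid arithmetic", {
  # 2-input / 2-hidden toy with hand-set weights, no normalizer
  m <- structure(
    list(W1 = matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2),
         b1 = c(0.1, -0.2), w2 = c(1.5, -2), b2 = 0.7,
         normalizer = NULL, feature_cols = c("x1", "x2"),
         target_col = "y", config = ann_config(hidden_n = 2),
         loss_trace = numeric(), n_train = 0L),
    class = "ann_model")
  x <- c(0.4, -1.2)
  h1 <- 1 / (1 + exp(-(0.5 * 0.4 - 0.3 * (-1.2) + 0.1)))
  h2 <- 1 / (1 + exp(-(0.2 * 0.4 + 0.8 * (-1.2) - 0.2)))
  want <- 1.5 * h1 - 2 * h2 + 0.7
  got <- predict(m, tibble::tibble(x1 = x[1], x2 = x[2]))
  expect_equal(got, want, tolerance = 1e-12)

  # zero weights: prediction is the output bias everywhere
  m$W1[] <- 0; m$b1[] <- 0; m$w2[] <- 0
  expect_equal(predict(m, tibble::tibble(x1 = rnorm(5), x2 = rnorm(5))),
               rep(0.7, 5))
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(13, {
    X <- matrix(runif(24), 8, 3)
    y <- rnorm(8)
    W1 <- matrix(rnorm(12, sd = 0.5), 3, 4)
    b1 <- rnorm(4, sd = 0.5); w2 <- rnorm(4, sd = 0.5); b2 <- rnorm(1)
  })
  decay <- 0.3
  gr <- wristmets:::ann_gradients(W1, b1, w2, b2, X, y, decay)
  eps <- 1e-6
  num_grad <- function(get, set) {
    th <- get()
    vapply(seq_along(th), function(i) {
      up <- th; up[i] <- up[i] + eps
      dn <- th; dn[i] <- dn[i] - eps
      (wristmets:::ann_loss(set(up)$W1, set(up)$b1, set(up)$w2, set(up)$b2,
                            X, y, decay) -
       wristmets:::ann_loss(set(dn)$W1, set(dn)$b1, set(dn)$w2, set(dn)$b2,
                            X, y, decay)) / (2 * eps)
    }, numeric(1))
  }
  pars <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  for (nm in names(pars)) {
    num <- num_grad(
      get = function() as.vector(pars[[nm]]),
      set = function(v) {
        p <- pars
        p[[nm]] <- if (nm == "W1") matrix(v, nrow(W1), ncol(W1)) else v
        p
      })
    ana <- as.vector(gr[[nm]])
    expect_lt(max(abs(ana - num)) / max(1, max(abs(ana))), 1e-6)
  }
})

test_that("increasing weight decay monotonically shrinks the weights", {
  d <- toy_data(100, noise_sd = 0.2)
  norms <- vapply(c(0, 0.5, 5, 50, 500), function(decay) {
    m <- train_ann(d, config = ann_config(hidden_n = 4, weight_decay = decay,
                                          max_iter = 800, seed = 3))
    sum(m$W1^2) + sum(m$w2^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("held-out RMSE on calibration pairs approaches the noise floor", {
  train <- generate_calibration_pairs(n = 560, noise_sd = 0.96, seed = 5)
  test <- generate_calibration_pairs(n = 560, noise_sd = 0.96, seed = 6)
  m <- train_ann(train, feature_cols = "mean", target_col = "mets",
                 config = ann_config(hidden_n = 8, weight_decay = 0))
  err <- sqrt(mean((predict(m, test) - test$mets)^2))
  expect_lt(abs(err - 0.96), 0.15 * 0.96)
})

test_that("our optimizer reaches nnet-comparable accuracy", {
  d <- toy_data(150, seed = 8, noise_sd = 0.3)
  ours <- train_ann(d, config = ann_config(hidden_n = 6, weight_decay = 0.1))
  ref <- withr::with_seed(8, nnet::nnet(
    x = as.matrix(d[feature_names()]), y = d$measured_mets, size = 6,
    decay = 0.1, linout = TRUE, maxit = 2000, trace = FALSE))
  rmse_ours <- sqrt(mean((predict(ours, d) - d$measured_mets)^2))
  rmse_ref <- sqrt(mean((predict(ref, as.matrix(d[feature_names()])) -
                           d$measured_mets)^2))
  expect_lt(rmse_ours, rmse_ref * 1.5 + 0.05)
})

test_that("tuning returns the argmin cell with a complete grid table", {
  d <- toy_data(60, noise_sd = 0.1)
  single <- tune_ann(d, decay_grid = 0.4, hidden_grid = 3, folds = 2,
                     base_config = ann_config(max_iter = 150))
  expect_equal(single$best_config$weight_decay, 0.4)
  expect_equal(single$best_config$hidden_n, 3L)
  expect_equal(nrow(single$grid), 1)

  # on noiseless linear data, no decay beats heavy decay
  d0 <- toy_data(80)
  tuned <- tune_ann(d0, decay_grid = c(0, 50), hidden_grid = 6, folds = 2,
                    base_config = ann_config(max_iter = 400))
  expect_equal(tuned$best_config$weight_decay, 0)
  expect_equal(nrow(tuned$grid), 2)
  expect_true(all(c("weight_decay", "hidden_n", "rmse") %in% names(tuned$grid)))
})

test_that("training input is validated", {
  d <- toy_data(20)
  expect_error(train_ann(d[0, ], config = ann_config()), "at least 2")
  d2 <- d; d2$measured_mets[3] <- NA
  expect_error(train_ann(d2), "index 3")
  expect_error(predict(train_ann(d, config = ann_config(max_iter = 10)),
                       d[, 1:3]), "Missing feature")
})
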