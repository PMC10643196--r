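#' Configuration for the single-hidden-layer network
#'
#' Hyperparameters of the feedforward METs regressor: one sigmoid hidden
#' layer, a linear output, full-batch gradient descent with an L2 penalty on
#' the weights ("weight attenuation"). The reference pooled model uses 8
#' hidden neurons and decay 0.8; the gait-specific models use 9/0.8 (walk)
#' and 4/0.7 (run). Training stops at `max_iter` (default 2000, the point at
#' which the reference models had converged) or when the loss improvement
#' drops below `tol`.
#'
#' The decay penalty follows the conventional single-hidden-layer convention
#' (total squared error plus `weight_decay * sum(w^2)`, biases excluded),
#' i.e. on the mean-loss scale the penalty is `weight_decay / n * sum(w^2)`.
#'
#' @param hidden_n Number of hidden neurons (1-30 in the tuning grid).
#' @param weight_decay L2 penalty strength; non-negative (tuning grid
#'   0.1-0.9).
#' @param max_iter Maximum gradient-descent iterations (default 2000).
#' @param learning_rate Initial step size (default 0.05). The step adapts
#'   deterministically: it is halved until a step no longer increases the
#'   penalized loss and grown by 10% after every accepted step, so the loss
#'   trace is non-increasing.
#' @param tol Convergence threshold on the loss improvement (default 1e-10).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden_n = 8, weight_decay = 0.8, max_iter = 2000,
                       learning_rate = 0.05, tol = 1e-10, seed = 1) {
  if (hidden_n < 1) abort("`hidden_n` must be >= 1.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (weight_decay < 0) abort("`weight_decay` must be non-negative.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(hidden_n = as.integer(hidden_n), weight_decay = weight_decay,
                 max_iter = as.integer(max_iter),
                 learning_rate = learning_rate, tol = tol,
                 seed = as.integer(seed)),
            class = "ann_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(W1, b1, w2, b2, X) {
  H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
  list(H = H, yhat = drop(H %*% w2) + b2)
}

# Penalized loss and its analytic gradients; the gradient-check test compares
# these against central finite differences.
ann_loss <- function(W1, b1, w2, b2, X, y, decay) {
  fw <- ann_forward(W1, b1, w2, b2, X)
  e <- fw$yhat - y
  n <- length(y)
  mean(e^2) + decay / n * (sum(W1^2) + sum(w2^2))
}

ann_gradients <- function(W1, b1, w2, b2, X, y, decay) {
  fw <- ann_forward(W1, b1, w2, b2, X)
  n <- length(y)
  g <- 2 * (fw$yhat - y) / n          # dL/d yhat
  H <- fw$H
  dw2 <- drop(crossprod(H, g)) + 2 * decay / n * w2
  db2 <- sum(g)
  dH <- outer(g, w2)
  dZ <- dH * H * (1 - H)
  dW1 <- crossprod(X, dZ) + 2 * decay / n * W1
  db1 <- colSums(dZ)
  list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2,
       loss = mean((fw$yhat - y)^2) + decay / n * (sum(W1^2) + sum(w2^2)))
}

ann_init <- function(n_in, hidden_n, seed) {
  withr::with_seed(seed, {
    list(
      W1 = matrix(runif(n_in * hidden_n, -0.5, 0.5) / sqrt(n_in),
                  n_in, hidden_n),
      b1 = runif(hidden_n, -0.5, 0.5) / sqrt(n_in),
      w2 = runif(hidden_n, -0.5, 0.5) / sqrt(hidden_n),
      b2 = 0
    )
  })
}

#' Train the single-hidden-layer METs regressor
#'
#' Fits the network by deterministic full-batch gradient descent on the
#' penalized loss (mean squared error plus the weight-decay L2 penalty;
#' biases are not penalized). Feature columns are min-max normalized with
#' bounds fitted on the training rows and stored in the model, so
#' [predict()] can be called on raw (unnormalized) feature tables. The run
#' is fully reproducible: the same data, configuration and seed give
#' bit-identical weights.
#'
#' @param data Data frame of training windows with feature columns and the
#'   target column; no missing values.
#' @param feature_cols Feature column names (default the nine window
#'   features; any number of features is accepted).
#' @param target_col Name of the measured-METs column (default
#'   `"measured_mets"`).
#' @param config An [ann_config()].
#' @param normalize Fit and store a min-max normalizer on the feature
#'   columns (default `TRUE`). Set to `FALSE` if the features are already
#'   normalized.
#' @return An object of class `ann_model`: weights, stored normalizer
#'   bounds, configuration and the loss trace.
#' @examples
#' d <- tibble::tibble(x1 = runif(100), x2 = runif(100))
#' d$y <- d$x1 + d$x2
#' m <- train_ann(d, feature_cols = c("x1", "x2"), target_col = "y",
#'                config = ann_config(hidden_n = 4, weight_decay = 0,
#'                                    max_iter = 500))
#' @export
train_ann <- function(data, feature_cols = feature_names(),
                      target_col = "measured_mets",
                      config = ann_config(), normalize = TRUE) {
  if (!inherits(config, "ann_config")) abort("`config` must be an `ann_config`.")
  miss <- setdiff(c(feature_cols, target_col), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  if (nrow(data) < 2) abort("Need at least 2 training rows.")
  y <- data[[target_col]]
  assert_finite(y, target_col)

  bounds <- NULL
  feats <- data[feature_cols]
  if (normalize) {
    bounds <- fit_normalizer(data, cols = feature_cols)
    feats <- apply_normalizer(feats, bounds)
  }
  X <- as.matrix(feats)
  if (anyNA(X)) abort("Features contain missing values.")

  par <- ann_init(ncol(X), config$hidden_n, config$seed)
  decay <- config$weight_decay
  lr <- config$learning_rate
  trace <- numeric(config$max_iter)
  loss <- ann_loss(par$W1, par$b1, par$w2, par$b2, X, y, decay)
  if (!is.finite(loss))
    abort(sprintf("Non-finite loss at initialization (hidden_n=%d, decay=%g).",
                  config$hidden_n, decay))

  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    gr <- ann_gradients(par$W1, par$b1, par$w2, par$b2, X, y, decay)
    # backtracking: halve the step until the penalized loss does not increase
    repeat {
      cand <- list(W1 = par$W1 - lr * gr$W1, b1 = par$b1 - lr * gr$b1,
                   w2 = par$w2 - lr * gr$w2, b2 = par$b2 - lr * gr$b2)
      new_loss <- ann_loss(cand$W1, cand$b1, cand$w2, cand$b2, X, y, decay)
      if (is.finite(new_loss) && new_loss <= loss) break
      lr <- lr / 2
      if (lr < 1e-14) break
    }
    if (lr < 1e-14) { trace <- trace[seq_len(n_iter)]; break }
    par <- cand
    lr <- lr * 1.1   # grow the step again after a successful move
    n_iter <- it
    trace[it] <- new_loss
    improved <- loss - new_loss
    loss <- new_loss
    if (!is.finite(loss))
      abort(sprintf("Training diverged (hidden_n=%d, decay=%g, lr=%g).",
                    config$hidden_n, decay, lr))
    if (improved < config$tol) { trace <- trace[seq_len(n_iter)]; break }
  }
  length(trace) <- n_iter

  structure(
    list(W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
         normalizer = bounds, feature_cols = feature_cols,
         target_col = target_col, config = config,
         loss_trace = trace, n_train = nrow(data)),
    class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model> %d-%d-1 network, decay %g, trained %d iterations on %d rows\n",
    nrow(x$W1), ncol(x$W1), x$config$weight_decay, length(x$loss_trace),
    x$n_train))
  invisible(x)
}

#' Predict METs with a trained network
#'
#' Forward pass: the model's stored min-max normalizer is applied to the
#' feature columns first, then `sigmoid(W1 x + b1)` and the linear output
#' layer. Validation rows outside the training feature range are normalized
#' without clipping (no warning here; the training-range check belongs to
#' [apply_normalizer()]).
#'
#' @param object An `ann_model` from [train_ann()].
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted METs.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss) > 0)
    abort(paste0("Missing feature column(s): ", paste(miss, collapse = ", "), "."))
  feats <- newdata[object$feature_cols]
  if (!is.null(object$normalizer))
    feats <- suppressWarnings(apply_normalizer(feats, object$normalizer))
  X <- as.matrix(feats)
  ann_forward(object$W1, object$b1, object$w2, object$b2, X)$yhat
}

#' @rdname tidy.ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble(hidden_n = ncol(x$W1), weight_decay = x$config$weight_decay,
         n_iter = length(x$loss_trace),
         final_loss = if (length(x$loss_trace)) tail(x$loss_trace, 1) else NA_real_,
         nobs = x$n_train)
}

#' Tidy the weights of a trained network
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per weight or bias (`layer`,
#'   `from`, `to`, `value`). `glance()`: a one-row fit summary.
#' @export
tidy.ann_model <- function(x, ...) {
  h <- ncol(x$W1)
  dplyr::bind_rows(
    tibble(layer = "hidden",
           from = rep(x$feature_cols, times = h),
           to = rep(paste0("h", seq_len(h)), each = nrow(x$W1)),
           value = as.vector(x$W1)),
    tibble(layer = "hidden", from = "bias",
           to = paste0("h", seq_len(h)), value = x$b1),
    tibble(layer = "output", from = paste0("h", seq_len(h)),
           to = "mets", value = x$w2),
    tibble(layer = "output", from = "bias", to = "mets", value = x$b2))
}

#' Grid-search the network hyperparameters by cross-validated RMSE
#'
#' Evaluates every (weight decay, hidden neurons) grid cell by k-fold
#' cross-validation on the training rows and returns the configuration with
#' the lowest mean RMSE. Ties are broken toward fewer hidden neurons, then
#' larger decay. The published tuning grid is decay 0.1-0.9 by 0.1 and
#' 1-30 hidden neurons; smaller grids are accepted.
#'
#' @inheritParams train_ann
#' @param decay_grid Numeric vector of weight-decay values.
#' @param hidden_grid Integer vector of hidden-layer sizes.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Seed for the fold assignment and per-fit initialization.
#' @param base_config An [ann_config()] providing the remaining settings
#'   (iterations, learning rate, tolerance).
#' @return A list of class `ann_tuning`: `$best_config` (an [ann_config()])
#'   and `$grid`, a tibble with columns `weight_decay`, `hidden_n`, `rmse`.
#' @export
tune_ann <- function(data, feature_cols = feature_names(),
                     target_col = "measured_mets",
                     decay_grid = seq(0.1, 0.9, by = 0.1),
                     hidden_grid = 1:30, folds = 5, seed = 1,
                     base_config = ann_config()) {
  if (length(decay_grid) == 0 || length(hidden_grid) == 0)
    abort("Grids must be non-empty.")
  if (folds < 2) abort("`folds` must be >= 2.")
  n <- nrow(data)
  if (n < 2 * folds) abort("Each fold needs at least 2 rows.")
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))

  cells <- tidyr::expand_grid(weight_decay = decay_grid, hidden_n = hidden_grid)
  cell_rmse <- purrr::pmap_dbl(cells, function(weight_decay, hidden_n) {
    errs <- vapply(seq_len(folds), function(k) {
      tr <- data[fold_id != k, , drop = FALSE]
      te <- data[fold_id == k, , drop = FALSE]
      cfg <- ann_config(hidden_n = hidden_n, weight_decay = weight_decay,
                        max_iter = base_config$max_iter,
                        learning_rate = base_config$learning_rate,
                        tol = base_config$tol, seed = seed + k)
      m <- train_ann(tr, feature_cols, target_col, cfg)
      pred <- predict(m, te)
      sqrt(mean((pred - te[[target_col]])^2))
    }, numeric(1))
    mean(errs)
  })
  grid <- dplyr::mutate(cells, rmse = cell_rmse)
  best <- grid |>
    dplyr::arrange(.data$rmse, .data$hidden_n, dplyr::desc(.data$weight_decay)) |>
    dplyr::slice(1)
  structure(
    list(best_config = ann_config(hidden_n = best$hidden_n,
                                  weight_decay = best$weight_decay,
                                  max_iter = base_config$max_iter,
                                  learning_rate = base_config$learning_rate,
                                  tol = base_config$tol, seed = seed),
         grid = grid),
    class = "ann_tuning")
}

#' @export
print.ann_tuning <- function(x, ...) {
  b <- x$best_config
  cat(sprintf("<ann_tuning> best: hidden_n = %d, decay = %g (grid of %d cells)\n",
              b$hidden_n, b$weight_decay, nrow(x$grid)))
  invisible(x)
}
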