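kind_n_coef <- c(linear = 2L, logarithmic = 2L, cubic = 4L)

#' Construct a closed-form Mean-to-METs regression model
#'
#' A regression model maps the window Mean (g) to energy expenditure in METs
#' through one of three closed forms:
#' \describe{
#'   \item{linear}{`METs = b1 * Mean + b0`, coefficients `(b1, b0)`}
#'   \item{logarithmic}{`METs = b1 * ln(Mean) + b0`, coefficients `(b1, b0)`}
#'   \item{cubic}{`METs = c3 Mean^3 + c2 Mean^2 + c1 Mean + c0`,
#'     coefficients `(c3, c2, c1, c0)`}
#' }
#'
#' @param kind One of `"linear"`, `"logarithmic"`, `"cubic"`.
#' @param coefficients Numeric vector in the order documented above (length 2
#'   for linear/logarithmic, 4 for cubic).
#' @param fitted_on Provenance tag (character), e.g. `"reference"` or a
#'   dataset label.
#' @return An object of class `ee_model`.
#' @seealso [ee_reference_model()] for the published reference coefficients.
#' @export
ee_model <- function(kind = c("linear", "logarithmic", "cubic"),
                     coefficients, fitted_on = "user") {
  kind <- match.arg(kind)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != kind_n_coef[[kind]])
    abort(sprintf("A %s model needs %d coefficients, got %d.",
                  kind, kind_n_coef[[kind]], length(coefficients)))
  assert_finite(coefficients, "coefficients")
  structure(list(kind = kind, coefficients = coefficients,
                 fitted_on = fitted_on),
            class = "ee_model")
}

#' Published reference regression models
#'
#' The three wrist-accelerometer Mean-to-METs equations with their published
#' coefficients, shipped as immutable reference models:
#' \itemize{
#'   \item linear: `METs = 8.33 Mean + 3.36` (R^2 0.856, SEE 0.96)
#'   \item logarithmic: `METs = 2.56 ln(Mean) + 10.04` (R^2 0.889, SEE 0.84)
#'   \item cubic: `METs = 29.65 Mean^3 - 52.67 Mean^2 + 33.46 Mean + 1.22`
#'     (R^2 0.891, SEE 0.83)
#' }
#' The published fit statistics are attached as attributes `r_squared` and
#' `see` for reference; they are not recomputed.
#'
#' @param kind One of `"linear"`, `"logarithmic"`, `"cubic"`.
#' @return An `ee_model` with `fitted_on = "reference"`.
#' @examples
#' predict(ee_reference_model("logarithmic"), 1)  # 10.04
#' @export
ee_reference_model <- function(kind = c("linear", "logarithmic", "cubic")) {
  kind <- match.arg(kind)
  ref <- switch(kind,
    linear      = list(coef = c(8.33, 3.36),                 r2 = 0.856, see = 0.96),
    logarithmic = list(coef = c(2.56, 10.04),                r2 = 0.889, see = 0.84),
    cubic       = list(coef = c(29.65, -52.67, 33.46, 1.22), r2 = 0.891, see = 0.83))
  m <- ee_model(kind, ref$coef, fitted_on = "reference")
  attr(m, "r_squared") <- ref$r2
  attr(m, "see") <- ref$see
  m
}

#' @export
print.ee_model <- function(x, ...) {
  co <- signif(x$coefficients, 6)
  expr <- switch(x$kind,
    linear = sprintf("METs = %g Mean + %g", co[1], co[2]),
    logarithmic = sprintf("METs = %g ln(Mean) + %g", co[1], co[2]),
    cubic = sprintf("METs = %g Mean^3 + %g Mean^2 + %g Mean + %g",
                    co[1], co[2], co[3], co[4]))
  cat(sprintf("<ee_model: %s> (%s)\n  %s\n", x$kind, x$fitted_on, expr))
  invisible(x)
}

#' Predict METs from window Means
#'
#' Evaluates the closed form exactly. The logarithmic model is only defined
#' for positive Means. Predictions are not clamped to a physiological range:
#' the cubic form in particular rises again beyond its second inflection (see
#' [cubic_inflection()]), and out-of-band predictions are reported as-is so
#' the caller can see them.
#'
#' @param object An [ee_model()].
#' @param newdata Numeric vector of window Means, or a data frame with a
#'   `mean` column.
#' @param ... Unused.
#' @return Numeric vector of predicted METs.
#' @export
predict.ee_model <- function(object, newdata, ...) {
  m <- if (is.data.frame(newdata)) {
    if (!"mean" %in% names(newdata)) abort("`newdata` must have a `mean` column.")
    newdata$mean
  } else as.numeric(newdata)
  if (object$kind == "logarithmic" && any(m <= 0))
    abort("The logarithmic model requires Mean > 0.")
  co <- object$coefficients
  switch(object$kind,
    linear = co[1] * m + co[2],
    logarithmic = co[1] * log(m) + co[2],
    cubic = ((co[1] * m + co[2]) * m + co[3]) * m + co[4])
}

#' Fit a Mean-to-METs regression by ordinary least squares
#'
#' Fits one of the three closed forms to pooled (Mean, METs) window pairs by
#' OLS (the logarithmic kind regresses METs on `ln(Mean)`). Reports the
#' goodness of fit as `R^2 = 1 - SSE/SST` and the standard error of estimate
#' `SEE = sqrt(SSE / (n - p))` with `p` the number of coefficients.
#'
#' @param data Data frame of training windows.
#' @param kind One of `"linear"`, `"logarithmic"`, `"cubic"`.
#' @param mean_col,mets_col Names of the predictor (window Mean) and response
#'   (measured METs) columns.
#' @return An object of class `ee_fit`: a list with the fitted `ee_model`
#'   (`$model`), `$r_squared`, `$see`, `$n`, and the underlying `lm` fit
#'   (`$fit`). Supports [tidy()], [glance()] and [predict()].
#' @examples
#' d <- tibble::tibble(mean = runif(50, 0.1, 0.9))
#' d$mets <- 8 * d$mean + 3 + rnorm(50, sd = 0.5)
#' fit <- fit_ee_regression(d, "linear")
#' glance(fit)
#' @export
fit_ee_regression <- function(data, kind = c("linear", "logarithmic", "cubic"),
                              mean_col = "mean", mets_col = "mets") {
  kind <- match.arg(kind)
  miss <- setdiff(c(mean_col, mets_col), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  x <- data[[mean_col]]
  y <- data[[mets_col]]
  p <- kind_n_coef[[kind]]
  if (length(x) < p + 1)
    abort(sprintf("Need at least %d pairs to fit a %s model.", p + 1, kind))
  if (kind == "logarithmic" && any(x <= 0))
    abort("The logarithmic model requires Mean > 0.")
  fit <- switch(kind,
    linear = lm(y ~ x),
    logarithmic = lm(y ~ log(x)),
    cubic = lm(y ~ poly(x, 3, raw = TRUE)))
  b <- unname(coef(fit))
  if (anyNA(b)) abort("Rank-deficient design; cannot fit.")
  coefs <- switch(kind,
    linear = c(b[2], b[1]),
    logarithmic = c(b[2], b[1]),
    cubic = c(b[4], b[3], b[2], b[1]))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(model = ee_model(kind, coefs, fitted_on = "fit"),
         r_squared = 1 - sse / sst,
         see = sqrt(sse / (length(y) - p)),
         n = length(y),
         fit = fit),
    class = "ee_fit")
}

#' @export
print.ee_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d, R^2 = %.4f, SEE = %.4f METs\n", x$n, x$r_squared, x$see))
  invisible(x)
}

#' @export
predict.ee_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' Tidy a fitted Mean-to-METs regression
#'
#' @param x An `ee_fit` from [fit_ee_regression()].
#' @param ... Unused.
#' @return `tidy()`: a tibble of coefficient estimates with standard errors
#'   (from the underlying OLS fit). `glance()`: a one-row tibble with
#'   `r.squared`, `see`, `nobs` and `kind`.
#' @export
tidy.ee_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  term <- switch(x$model$kind,
    linear = c("intercept", "mean"),
    logarithmic = c("intercept", "log(mean)"),
    cubic = c("intercept", "mean", "mean^2", "mean^3"))
  tibble(term = term, estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @rdname tidy.ee_fit
#' @export
glance.ee_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, see = x$see, nobs = x$n,
         kind = x$model$kind)
}

#' Inflection point of a cubic Mean-to-METs model
#'
#' The cubic form flattens and then rises again; the root of its second
#' derivative, `-c2 / (3 c3)`, marks the Mean beyond which predicted energy
#' expenditure accelerates upward. For the published reference cubic this is
#' about 0.59, so predictions above that Mean should be treated with caution.
#'
#' @param model A cubic [ee_model()].
#' @return The inflection Mean (g).
#' @examples
#' cubic_inflection(ee_reference_model("cubic"))
#' @export
cubic_inflection <- function(model) {
  if (!inherits(model, "ee_model")) {
    if (inherits(model, "ee_fit")) model <- model$model
    else abort("`model` must be an `ee_model` or `ee_fit`.")
  }
  if (model$kind != "cubic") abort("`cubic_inflection()` requires a cubic model.")
  co <- model$coefficients
  if (co[1] == 0) abort("Leading coefficient is zero; not a cubic.")
  -co[2] / (3 * co[1])
}
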