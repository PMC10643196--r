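#' Read a delimited accelerometer log
#'
#' Reads a raw tri-axial log (header row; columns `time`, `ax`, `ay`, `az`
#' in any order; optional `subject`, `speed_kmh`, `gait`) into a validated
#' stream tibble. Units are g; `time` is seconds as a decimal number. Column
#' order is irrelevant — parsing is header-driven. Non-numeric cells,
#' missing columns, non-monotone time, or (when `rate` is given) a sample
#' gap beyond 10% of the nominal interval are rejected with the offending
#' line or timestamp named.
#'
#' @param path File path.
#' @param delim Field delimiter (default `","`).
#' @param rate Optional nominal sampling rate in Hz; when given, timing
#'   jitter beyond 10% is an error.
#' @param quiet Suppress the row-count/duration message (default `FALSE`).
#' @return A stream tibble with columns `t`, `ax`, `ay`, `az` and any label
#'   columns.
#' @export
read_accel_log <- function(path, delim = ",", rate = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("time", "ax", "ay", "az")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    abort(paste0("Log is missing column(s): ", paste(miss, collapse = ", "), "."))
  for (col in need) {
    if (!is.numeric(raw[[col]])) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]))
      if (length(bad) > 0)
        abort(sprintf("Non-numeric value in column `%s` at line %d.",
                      col, bad[1] + 1L))  # +1 for the header row
      raw[[col]] <- v
    }
    if (anyNA(raw[[col]]))
      abort(sprintf("Missing value in column `%s` at line %d.",
                    col, which(is.na(raw[[col]]))[1] + 1L))
  }
  stream <- tibble(t = raw$time, ax = raw$ax, ay = raw$ay, az = raw$az)
  for (col in c("subject", "speed_kmh", "gait"))
    if (col %in% names(raw)) stream[[col]] <- raw[[col]]
  validate_stream(stream, rate = rate)
  if (!quiet)
    rlang::inform(sprintf("Read %d samples spanning %.2f s (units: g).",
                          nrow(stream), diff(range(stream$t))))
  stream
}

#' Write / read a feature or VM table
#'
#' Plain CSV round-trip for the tabular artifacts of the pipeline (VM
#' series, window feature tables, per-speed error tables).
#'
#' @param data A data frame.
#' @param path File path.
#' @return `write_table()` returns `data` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

## ---- model serialization ---------------------------------------------------

serialize_obj <- function(x) {
  if (inherits(x, "ee_model")) {
    list(type = "ee_model", kind = x$kind, coefficients = x$coefficients,
         fitted_on = x$fitted_on)
  } else if (inherits(x, "ee_fit")) {
    list(type = "ee_fit", model = serialize_obj(x$model),
         r_squared = x$r_squared, see = x$see, n = x$n)
  } else if (inherits(x, "minmax_normalizer")) {
    list(type = "minmax_normalizer", cols = x$cols,
         x_min = unname(x$x_min), x_max = unname(x$x_max))
  } else if (inherits(x, "ann_config")) {
    c(list(type = "ann_config"), unclass(x))
  } else if (inherits(x, "ann_model")) {
    list(type = "ann_model",
         dim = dim(x$W1), W1 = as.vector(x$W1), b1 = x$b1,
         w2 = x$w2, b2 = x$b2,
         normalizer = if (is.null(x$normalizer)) NULL
                      else serialize_obj(x$normalizer),
         feature_cols = x$feature_cols, target_col = x$target_col,
         config = serialize_obj(x$config),
         loss_trace = x$loss_trace, n_train = x$n_train)
  } else if (inherits(x, "cutoff_model")) {
    c(list(type = "cutoff_model"), unclass(x))
  } else if (inherits(x, "two_stage_model")) {
    list(type = "two_stage_model", cutoff = serialize_obj(x$cutoff),
         walk_model = serialize_obj(x$walk_model),
         run_model = serialize_obj(x$run_model),
         feature_cols = x$feature_cols, target_col = x$target_col,
         mean_col = x$mean_col, gait_col = x$gait_col)
  } else if (inherits(x, "eval_report")) {
    ba <- x$bland_altman
    list(type = "eval_report",
         overall = as.list(x$overall),
         per_gait = if (is.null(x$per_gait)) NULL else as.list(x$per_gait),
         per_speed = if (is.null(x$per_speed)) NULL else as.list(x$per_speed),
         bland_altman = if (is.null(ba)) NULL else
           list(mean_diff = ba$mean_diff, loa_low = ba$loa_low,
                loa_high = ba$loa_high, n_outside = ba$n_outside,
                frac_outside = ba$frac_outside, n = ba$n,
                points = as.list(ba$points)),
         bias_mode = x$bias_mode)
  } else {
    abort(paste0("Don't know how to serialize an object of class ",
                 paste(class(x), collapse = "/"), "."))
  }
}

deserialize_obj <- function(o) {
  if (is.null(o$type)) abort("Corrupted document: missing `type` field.")
  switch(o$type,
    ee_model = ee_model(o$kind, o$coefficients, o$fitted_on),
    ee_fit = structure(
      list(model = deserialize_obj(o$model), r_squared = o$r_squared,
           see = o$see, n = o$n, fit = NULL),
      class = "ee_fit"),
    minmax_normalizer = structure(
      list(cols = o$cols, x_min = setNames(o$x_min, o$cols),
           x_max = setNames(o$x_max, o$cols)),
      class = "minmax_normalizer"),
    ann_config = ann_config(o$hidden_n, o$weight_decay, o$max_iter,
                            o$learning_rate, o$tol, o$seed),
    ann_model = structure(
      list(W1 = matrix(o$W1, o$dim[1], o$dim[2]), b1 = o$b1, w2 = o$w2,
           b2 = o$b2,
           normalizer = if (is.null(o$normalizer)) NULL
                        else deserialize_obj(o$normalizer),
           feature_cols = o$feature_cols, target_col = o$target_col,
           config = deserialize_obj(o$config),
           loss_trace = o$loss_trace, n_train = o$n_train),
      class = "ann_model"),
    cutoff_model = structure(
      list(threshold = o$threshold, youden_j = o$youden_j, auc = o$auc,
           positive = o$positive),
      class = "cutoff_model"),
    two_stage_model = structure(
      list(cutoff = deserialize_obj(o$cutoff),
           walk_model = deserialize_obj(o$walk_model),
           run_model = deserialize_obj(o$run_model),
           feature_cols = o$feature_cols, target_col = o$target_col,
           mean_col = o$mean_col, gait_col = o$gait_col),
      class = "two_stage_model"),
    eval_report = structure(
      list(overall = as_tibble(o$overall),
           per_gait = if (is.null(o$per_gait)) NULL else as_tibble(o$per_gait),
           per_speed = if (is.null(o$per_speed)) NULL else as_tibble(o$per_speed),
           bland_altman = if (is.null(o$bland_altman)) NULL else
             structure(
               list(mean_diff = o$bland_altman$mean_diff,
                    loa_low = o$bland_altman$loa_low,
                    loa_high = o$bland_altman$loa_high,
                    n_outside = o$bland_altman$n_outside,
                    frac_outside = o$bland_altman$frac_outside,
                    n = o$bland_altman$n,
                    points = as_tibble(o$bland_altman$points)),
               class = "bland_altman"),
           bias_mode = o$bias_mode),
      class = "eval_report"),
    abort(paste0("Corrupted document: unknown type `", o$type, "`."))
  )
}

#' Save / load a model or report as JSON
#'
#' Serializes any fitted artifact of the package (closed-form models and
#' fits, normalizers, network models and configurations, cut-point models,
#' the composite two-stage model, evaluation reports) to a structured JSON
#' document at full floating-point precision, so that reloaded models give
#' bit-identical predictions. A reloaded `ee_fit` keeps its coefficients and
#' fit statistics but not the underlying `lm` object.
#'
#' @param x The object to save.
#' @param path File path (conventionally `.json`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   reconstructed object.
#' @examples
#' p <- tempfile(fileext = ".json")
#' save_model(ee_reference_model("cubic"), p)
#' load_model(p)
#' @export
save_model <- function(x, path) {
  # I(17): 17 significant digits, enough for exact double round-trips
  jsonlite::write_json(serialize_obj(x), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  o <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) abort(paste0("Corrupted document: ",
                                                 conditionMessage(e))))
  deserialize_obj(o)
}
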