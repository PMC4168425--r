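# CSV / JSON interfaces: mixture tables in, fitted models out and back.

#' Read a binary-mixture observation table from CSV
#'
#' Expected columns: `sample_id`, `odorant_a`, `odorant_b`, `ln_oav_a`,
#' `ln_oav_b`, `oi`. `oi` may be blank for prediction-only rows.
#'
#' @param file path to a UTF-8 CSV file with a header row.
#' @return a data.frame.
#' @export
read_mixtures <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "odorant_a", "odorant_b", "ln_oav_a", "ln_oav_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_odormix("odormix_schema_error",
                 paste0("mixtures CSV is missing column(s): ",
                        paste(miss, collapse = ", ")))
  if (!nrow(df))
    stop_odormix("odormix_schema_error", "mixtures CSV contains no rows")
  for (col in c("ln_oav_a", "ln_oav_b")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop_odormix("odormix_schema_error",
                   sprintf("non-numeric %s in row(s) %s", col,
                           paste(bad, collapse = ", ")))
  }
  if (!"oi" %in% names(df)) df$oi <- NA_real_
  df
}

#' Write or read a fitted interaction curve as JSON
#'
#' The JSON stores mixture label, components, axis orientation, family,
#' coefficients, R^2, number of points and the symmetry flag — everything
#' needed to predict, but not the raw data or the fit object, so a
#' round-tripped curve predicts identically yet cannot produce new
#' prediction intervals.
#'
#' @param curve an [interaction_curve()].
#' @param file output path.
#' @return `write_model`: the path, invisibly. `read_model`: an
#'   [interaction_curve()].
#' @export
write_model <- function(curve, file) {
  if (!inherits(curve, "interaction_curve"))
    abort_invalid("'curve' must be an interaction_curve")
  obj <- list(
    mixture = curve$label,
    components = as.list(curve$components),
    axis_component = curve$axis_component,
    family = curve$family,
    coefficients = as.list(curve$coefficients),
    r_squared = curve$r_squared,
    n_points = curve$n_points,
    symmetric = curve$symmetric
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  interaction_curve(
    unlist(obj$coefficients), family = obj$family,
    components = unlist(obj$components),
    axis_component = obj$axis_component,
    label = if (is.null(obj$mixture)) NULL else obj$mixture,
    r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared,
    n_points = if (is.null(obj$n_points)) NA_integer_ else obj$n_points,
    symmetric = isTRUE(obj$symmetric)
  )
}
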