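# OIRS scale handling, panel aggregation and the linear OI ~ lnOAV
# calibration for individual odorants. Panel ratings are matched against an
# aqueous 1-butanol ladder (the odor intensity referencing scale); assessors
# may use half-point scores, so the admissible grid is 0, 0.5, ..., 8.

OIRS_MAX <- 8

#' The 1-butanol odor intensity referencing scale
#'
#' Level k of the OIRS is an aqueous 1-butanol solution at 12 x 2^(k-1) ppm:
#' a geometric ladder doubling per level, starting from 12 ppm at level 1.
#'
#' @param levels number of scale levels (>= 1), default 8.
#' @return a data.frame with columns `level` and `butanol_ppm`.
#' @export
#' @examples
#' oirs_ladder()
oirs_ladder <- function(levels = 8) {
  if (!is_scalar_number(levels) || levels < 1 || levels != round(levels))
    abort_invalid("'levels' must be a positive integer")
  k <- seq_len(levels)
  data.frame(level = k, butanol_ppm = 12 * 2^(k - 1))
}

#' Per-assessor OIRS scores for one odor sample
#'
#' @param sample_id sample identifier.
#' @param scores numeric vector of OIRS scores, one per assessor; each must
#'   lie in \[0, 8\]. Scores are expected on the half-point grid
#'   (multiples of 0.5); off-grid scores trigger a warning, or an error
#'   when `strict = TRUE`.
#' @param strict escalate grid violations from warning to error.
#' @return an object of class `"panel_record"`.
#' @export
#' @examples
#' aggregate_panel(panel_record("s1", c(2.0, 2.5, 3.0, 3.5, 4.0)))
panel_record <- function(sample_id, scores, strict = FALSE) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    abort_invalid("'sample_id' must be a single string")
  if (!is.numeric(scores) || length(scores) < 1L)
    abort_invalid("'scores' must contain at least one numeric score")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > OIRS_MAX))
    abort_invalid("all scores must lie within [0, 8] on the OIRS")
  off_grid <- abs(scores * 2 - round(scores * 2)) > 1e-9
  if (any(off_grid)) {
    msg <- paste0("score(s) not on the 0.5-point OIRS grid: ",
                  paste(format(scores[off_grid]), collapse = ", "))
    if (strict) abort_invalid(msg) else warning(msg, call. = FALSE)
  }
  structure(list(sample_id = sample_id, scores = as.numeric(scores)),
            class = "panel_record")
}

#' Aggregate a panel record into one odor intensity
#'
#' A sample's odor intensity is the arithmetic mean of all scores rated by
#' the assessors in its panel.
#'
#' @param record a [panel_record()].
#' @return a list of class `"oi_measurement"` with `sample_id`, `oi`
#'   (panel mean) and `n_assessors`.
#' @export
aggregate_panel <- function(record) {
  if (!inherits(record, "panel_record"))
    abort_invalid("'record' must be a panel_record")
  structure(
    list(sample_id = record$sample_id,
         oi = mean(record$scores),
         n_assessors = length(record$scores)),
    class = "oi_measurement"
  )
}

#' @export
print.oi_measurement <- function(x, ...) {
  cat("<oi_measurement> ", x$sample_id, ": OI = ", format(x$oi),
      " (", x$n_assessors, " assessors)\n", sep = "")
  invisible(x)
}

#' Fit the linear odor intensity law for one odorant
#'
#' For an individual odorant, panel odor intensity is linear in the natural
#' log of the odor activity value (a Weber-Fechner-type law on the OAV
#' scale): OI = slope * lnOAV + intercept, fitted by ordinary least squares.
#'
#' @param ln_oav numeric vector of lnOAV values (>= 2 distinct values).
#' @param oi numeric vector of panel-mean odor intensities, same length.
#' @param odorant_name optional label stored with the model.
#' @return an object of class `"oi_line"` with `slope`, `intercept`,
#'   `r_squared`, `n_points` and the underlying [stats::lm] fit.
#' @seealso [predict_individual()]
#' @export
#' @examples
#' fit_individual(c(1, 2, 3), c(1.3, 2.2, 3.1))
fit_individual <- function(ln_oav, oi, odorant_name = NULL) {
  if (length(ln_oav) != length(oi))
    abort_invalid("'ln_oav' and 'oi' must have the same length")
  if (length(ln_oav) < 2L)
    abort_invalid("at least two points are required")
  if (length(unique(ln_oav)) < 2L)
    abort_degenerate("all lnOAV values are identical; the line is not identifiable")
  fit <- stats::lm(oi ~ ln_oav, data = data.frame(ln_oav = ln_oav, oi = oi))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((oi - mean(oi))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(
    list(odorant = odorant_name,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2, n_points = length(oi), fit = fit),
    class = "oi_line"
  )
}

#' @export
print.oi_line <- function(x, ...) {
  lbl <- if (is.null(x$odorant)) "" else paste0(" [", x$odorant, "]")
  cat("<oi_line>", lbl, " OI = ", format(x$slope, digits = 4), " * lnOAV + ",
      format(x$intercept, digits = 4),
      "  (R^2 = ", format(x$r_squared, digits = 4),
      ", n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Predict an individual odorant's odor intensity
#'
#' Evaluates the fitted line and floors the result at 0: a single odorant's
#' perceived intensity cannot be negative. (Mixture partial differential
#' OIs, by contrast, are deliberately not floored — see
#' [tangent_decompose()].)
#'
#' @param model an `"oi_line"` from [fit_individual()].
#' @param ln_oav numeric vector of lnOAV values.
#' @return predicted odor intensities, >= 0.
#' @export
predict_individual <- function(model, ln_oav) {
  if (!inherits(model, "oi_line"))
    abort_invalid("'model' must come from fit_individual()")
  pmax(0, model$slope * ln_oav + model$intercept)
}

#' Read per-assessor panel scores from CSV and aggregate per sample
#'
#' Expected columns: `sample_id`, `assessor_id`, `score`.
#'
#' @param file path to a CSV file.
#' @param strict escalate half-point grid violations to errors.
#' @return a data.frame with one row per sample: `sample_id`, `oi`,
#'   `n_assessors`.
#' @export
read_panel <- function(file, strict = FALSE) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "assessor_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_invalid(paste0("panel CSV is missing column(s): ",
                         paste(miss, collapse = ", ")))
  ids <- unique(df$sample_id)
  rows <- lapply(ids, function(id) {
    rec <- panel_record(as.character(id), df$score[df$sample_id == id],
                        strict = strict)
    m <- aggregate_panel(rec)
    data.frame(sample_id = m$sample_id, oi = m$oi,
               n_assessors = m$n_assessors)
  })
  do.call(rbind, rows)
}
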