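# Odorant identities, concentration units, odor thresholds and odor
# activity values (OAV). The OAV is the ratio of an odorant's chemical
# concentration to its odor detection threshold; its natural logarithm is
# the dose scale on which odor intensity is linear for individual odorants.

#' Describe an odorant
#'
#' Bundles an odorant's identity with its odor detection threshold (the
#' lowest concentration perceivable by smell) and, optionally, its molecular
#' weight for mg/m3 <-> ppm conversion. The threshold anchors all odor
#' activity value computations and is stored in mg/m3, the package's
#' canonical concentration unit.
#'
#' @param name odorant name, e.g. `"benzene"`.
#' @param threshold odor threshold. Either a plain number in mg/m3 or a
#'   [concentration()] object (converted to mg/m3; ppm thresholds require
#'   `molecular_weight`).
#' @param cas optional CAS registry number.
#' @param molecular_weight optional molecular weight in g/mol (> 0);
#'   required only for mg/m3 <-> ppm conversion.
#' @return an object of class `"odorant"`.
#' @seealso [compute_oav()], [convert_concentration()], [read_odorants()]
#' @export
#' @examples
#' benzene <- odorant("benzene", threshold = 2.13, cas = "71-43-2",
#'                    molecular_weight = 78.11)
#' compute_oav(concentration(61.3, "g/m3"), benzene)
odorant <- function(name, threshold, cas = NULL, molecular_weight = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_invalid("'name' must be a non-empty string")
  if (!is.null(molecular_weight)) {
    if (!is_scalar_number(molecular_weight) || molecular_weight <= 0)
      abort_invalid("'molecular_weight' must be a single positive number (g/mol)")
  }
  if (inherits(threshold, "concentration")) {
    threshold <- convert_concentration(
      threshold, "mg/m3",
      odorant = list(molecular_weight = molecular_weight)
    )$value
  }
  if (!is_scalar_number(threshold) || threshold <= 0)
    abort_invalid("'threshold' must be a single strictly positive number (mg/m3)")
  structure(
    list(name = name, cas = cas, molecular_weight = molecular_weight,
         threshold = threshold),
    class = "odorant"
  )
}

#' @export
print.odorant <- function(x, ...) {
  cat("<odorant> ", x$name, sep = "")
  if (!is.null(x$cas)) cat(" (CAS ", x$cas, ")", sep = "")
  cat("\n  odor threshold: ", format(x$threshold), " mg/m3\n", sep = "")
  if (!is.null(x$molecular_weight))
    cat("  molecular weight: ", format(x$molecular_weight), " g/mol\n", sep = "")
  invisible(x)
}

#' Gas-phase concentration with units
#'
#' @param value non-negative numeric value.
#' @param units one of `"mg/m3"`, `"g/m3"`, `"ppm"`.
#' @return an object of class `"concentration"`.
#' @export
#' @examples
#' concentration(5.8, "g/m3")
concentration <- function(value, units = c("mg/m3", "g/m3", "ppm")) {
  units <- match.arg(units)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    abort_invalid("'value' must be a single non-negative number")
  structure(list(value = value, units = units), class = "concentration")
}

#' @export
print.concentration <- function(x, ...) {
  cat("<concentration> ", format(x$value), " ", x$units, "\n", sep = "")
  invisible(x)
}

#' Convert a concentration between mg/m3, g/m3 and ppm
#'
#' g/m3 <-> mg/m3 is an exact factor of 1000. mg/m3 <-> ppm uses the ideal
#' gas relation ppm = mg/m3 x Vm / MW with molar volume `Vm` in L/mol
#' (default 24.45, i.e. 25 degC at 1 atm) and the odorant's molecular
#' weight in g/mol.
#'
#' @param x a [concentration()].
#' @param target_units one of `"mg/m3"`, `"g/m3"`, `"ppm"`.
#' @param odorant an [odorant()] (or list) carrying `molecular_weight`;
#'   required only when converting to or from ppm.
#' @param molar_volume_L_per_mol molar volume used for the gas conversion.
#' @return a [concentration()] in `target_units`.
#' @export
#' @examples
#' eb <- odorant("ethylbenzene", 0.25, molecular_weight = 106.17)
#' convert_concentration(concentration(0.25, "mg/m3"), "ppm", eb)
convert_concentration <- function(x, target_units = c("mg/m3", "g/m3", "ppm"),
                                  odorant = NULL,
                                  molar_volume_L_per_mol = 24.45) {
  target_units <- match.arg(target_units)
  if (!inherits(x, "concentration"))
    abort_invalid("'x' must be a concentration object")
  if (x$units == target_units) return(x)

  mw <- odorant$molecular_weight
  to_mg <- function(c) {
    switch(c$units,
      "mg/m3" = c$value,
      "g/m3"  = c$value * 1000,
      "ppm"   = {
        if (is.null(mw))
          abort_missing("molecular_weight is required to convert ppm to mg/m3")
        c$value * mw / molar_volume_L_per_mol
      }
    )
  }
  mg <- to_mg(x)
  out <- switch(target_units,
    "mg/m3" = mg,
    "g/m3"  = mg / 1000,
    "ppm"   = {
      if (is.null(mw))
        abort_missing("molecular_weight is required to convert mg/m3 to ppm")
      mg * molar_volume_L_per_mol / mw
    }
  )
  concentration(out, target_units)
}

#' Odor activity value of a gas sample
#'
#' The odor activity value is OAV = C / C_thr, the ratio of a sample's
#' chemical concentration to the odorant's odor threshold, both in mg/m3.
#' Its natural logarithm, lnOAV, is the dose scale used throughout the
#' interaction model: lnOAV > 0 means the component is above threshold.
#'
#' @param conc the sample concentration, a [concentration()] or a plain
#'   number in mg/m3; must be strictly positive.
#' @param odorant the [odorant()] supplying the threshold (and molecular
#'   weight if a ppm concentration must be converted).
#' @param molar_volume_L_per_mol molar volume forwarded to unit conversion.
#' @return a list of class `"oav_record"` with elements `oav` and `ln_oav`.
#' @export
#' @examples
#' b <- odorant("benzene", 2.13)
#' compute_oav(concentration(61.3, "g/m3"), b) # OAV ~ 28779, lnOAV ~ 10.27
compute_oav <- function(conc, odorant, molar_volume_L_per_mol = 24.45) {
  if (is.numeric(conc)) conc <- concentration(conc, "mg/m3")
  if (!inherits(odorant, "odorant"))
    abort_invalid("'odorant' must be an odorant object")
  if (conc$value <= 0)
    abort_invalid("concentration must be strictly positive to form an OAV")
  mg <- convert_concentration(conc, "mg/m3", odorant,
                              molar_volume_L_per_mol)$value
  oav <- mg / odorant$threshold
  structure(list(oav = oav, ln_oav = log(oav)), class = "oav_record")
}

#' @export
print.oav_record <- function(x, ...) {
  cat("<oav_record> OAV = ", format(x$oav),
      ", lnOAV = ", format(x$ln_oav), "\n", sep = "")
  invisible(x)
}

#' Odor threshold from a forced-choice dilution series
#'
#' In dynamic olfactometry each assessor smells an ascending dilution
#' series until they can no longer pick the odor from blanks; the recorded
#' dilution multiple is the factor at which the sample became odorless for
#' them. The panel threshold is the initial concentration divided by the
#' average of all recorded dilution multiples.
#'
#' @param initial_concentration starting concentration, a [concentration()]
#'   or a number in mg/m3.
#' @param dilution_multiples numeric vector of recorded dilution multiples,
#'   all > 1; one entry per assessor (or per repeat).
#' @param average `"arithmetic"` (default) or `"geometric"`; olfactometry
#'   standards often average dilution steps geometrically, so that option
#'   is exposed too.
#' @return a [concentration()] in the units of `initial_concentration`.
#' @export
#' @examples
#' threshold_from_panel(100, c(50, 100, 150)) # 1 mg/m3
threshold_from_panel <- function(initial_concentration, dilution_multiples,
                                 average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (is.numeric(initial_concentration))
    initial_concentration <- concentration(initial_concentration, "mg/m3")
  if (length(dilution_multiples) < 1L)
    abort_invalid("at least one dilution multiple is required")
  if (!is.numeric(dilution_multiples) || any(!is.finite(dilution_multiples)) ||
      any(dilution_multiples <= 1))
    abort_invalid("dilution multiples must all be finite numbers > 1")
  m <- switch(average,
    arithmetic = mean(dilution_multiples),
    geometric  = exp(mean(log(dilution_multiples)))
  )
  concentration(initial_concentration$value / m, initial_concentration$units)
}

#' Read an odorant table from CSV
#'
#' Expected columns: `name`, `threshold_mg_m3` (required), `cas`,
#' `molecular_weight` (optional; empty cells allowed).
#'
#' @param file path to a UTF-8 CSV file with a header row.
#' @return a named list of [odorant()] objects.
#' @export
read_odorants <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "threshold_mg_m3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_invalid(paste0("odorants CSV is missing column(s): ",
                         paste(miss, collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i) {
    mw <- if ("molecular_weight" %in% names(df)) df$molecular_weight[i] else NULL
    if (!is.null(mw) && (is.na(mw))) mw <- NULL
    cas <- if ("cas" %in% names(df)) df$cas[i] else NULL
    if (!is.null(cas) && (is.na(cas) || !nzchar(cas))) cas <- NULL
    odorant(df$name[i], threshold = df$threshold_mg_m3[i],
            cas = cas, molecular_weight = mw)
  })
  names(out) <- df$name
  out
}
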