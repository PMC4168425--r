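# The tangent-intercept (partial differential) machinery itself: the
# coordinate transform into (mixing proportion, averaged OI) space, the
# tangent decomposition that yields per-component partial differential
# odor intensities, and mixture OI prediction.
#
# Transform:  OI_m = OI / (lnOAV_a + lnOAV_b),  x_a = lnOAV_a / (lnOAV_a + lnOAV_b)
# Tangent at (x', y') on the fitted curve f:
#   intercept at x = 1:  OI_axis,m  = (1 - x') f'(x') + y'
#   intercept at x = 0:  OI_other,m = -x' f'(x') + y'
# Prediction:  OI = OI_a,m lnOAV_a + OI_b,m lnOAV_b,
# which collapses algebraically to (lnOAV_a + lnOAV_b) f(x).

#' Transform binary mixture observations into interaction-curve space
#'
#' Each observation carries both components' lnOAV and a panel-mean odor
#' intensity. The transform divides OI by the total lnOAV (giving the
#' averaged OI, the vertical coordinate) and expresses the axis component's
#' lnOAV as a share of that total (the mixing proportion, the horizontal
#' coordinate). Both components must be above threshold (lnOAV > 0).
#'
#' @param mixtures a data.frame with columns `ln_oav_a`, `ln_oav_b`, `oi`
#'   and optionally `sample_id`, `odorant_a`, `odorant_b`.
#' @param axis_component which component's proportion is the horizontal
#'   coordinate: `"a"`, `"b"`, or an odorant name appearing in the
#'   `odorant_a`/`odorant_b` columns (the same one for every row).
#' @return the input data.frame with columns `x` (mixing proportion of the
#'   axis component) and `oi_m` (averaged OI) appended.
#' @seealso [fit_pde()], [predict_oi()]
#' @export
#' @examples
#' m <- data.frame(ln_oav_a = 3.36, ln_oav_b = 2.24, oi = 4.8)
#' pde_transform(m, "a")  # x = 0.6
pde_transform <- function(mixtures, axis_component = "a") {
  mixtures <- as.data.frame(mixtures)
  need <- c("ln_oav_a", "ln_oav_b", "oi")
  miss <- setdiff(need, names(mixtures))
  if (length(miss))
    abort_invalid(paste0("mixtures need column(s): ", paste(miss, collapse = ", ")))
  axis <- resolve_axis(mixtures, axis_component)
  la <- mixtures$ln_oav_a
  lb <- mixtures$ln_oav_b
  if (any(!is.finite(la)) || any(!is.finite(lb)))
    abort_invalid("lnOAV values must be finite")
  if (any(la <= 0) || any(lb <= 0))
    abort_subthreshold(
      "all components must be above threshold (lnOAV > 0) for the transform")
  total <- la + lb
  if (any(total <= 0))
    abort_invalid("total lnOAV must be positive")
  if (any(!is.finite(mixtures$oi)))
    abort_invalid("'oi' must be present and finite for every observation")
  ln_axis <- if (axis == "a") la else lb
  mixtures$x <- ln_axis / total
  mixtures$oi_m <- mixtures$oi / total
  mixtures
}

# map an axis_component spec ("a", "b" or an odorant name) to "a"/"b"
resolve_axis <- function(mixtures, axis_component) {
  if (!is.character(axis_component) || length(axis_component) != 1L)
    abort_invalid("'axis_component' must be a single string")
  if (axis_component %in% c("a", "b")) return(axis_component)
  has_names <- all(c("odorant_a", "odorant_b") %in% names(mixtures))
  if (!has_names)
    abort_invalid(
      "'axis_component' names an odorant but the mixtures lack odorant_a/odorant_b columns")
  in_a <- mixtures$odorant_a == axis_component
  in_b <- mixtures$odorant_b == axis_component
  if (all(in_a)) "a"
  else if (all(in_b)) "b"
  else abort_invalid(sprintf(
    "'%s' must appear in the same position (odorant_a or odorant_b) for every row",
    axis_component))
}

#' Tangent decomposition at a point of the interaction curve
#'
#' Draws the tangent line to the curve at x'. Its intercepts on the two
#' vertical axes are the partial differential odor intensities: the
#' intercept at x = 1 (`oi_axis_m`) belongs to the axis component, the
#' intercept at x = 0 (`oi_other_m`) to the partner. Each is the change of
#' the mixture's OI per unit lnOAV of that component; near the ends of the
#' mixing range one of them can legitimately be negative, so intercepts
#' are returned unfloored (with an advisory `negative` flag).
#'
#' @param curve an [interaction_curve()].
#' @param x_prime tangency point, strictly inside (0, 1). Vectorized.
#' @return an object of class `"tangent_decomposition"`: a data.frame with
#'   columns `x_prime`, `y_prime`, `slope`, `oi_axis_m`, `oi_other_m`,
#'   `negative`.
#' @export
#' @examples
#' bt <- interaction_curve(c(1.93, -2.09, 1.39))
#' tangent_decompose(bt, 0.6)  # y' = 0.83, slope = 0.23
tangent_decompose <- function(curve, x_prime) {
  if (!inherits(curve, "interaction_curve"))
    abort_invalid("'curve' must be an interaction_curve")
  if (!is.numeric(x_prime) || any(!is.finite(x_prime)))
    abort_invalid("'x_prime' must be numeric and finite")
  if (any(x_prime <= 0) || any(x_prime >= 1))
    abort_domain("'x_prime' must lie strictly inside (0, 1)")
  y_prime <- curve_value(curve, x_prime)
  slope <- curve_slope(curve, x_prime)
  oi_axis_m <- (1 - x_prime) * slope + y_prime
  oi_other_m <- -x_prime * slope + y_prime
  out <- data.frame(
    x_prime = x_prime, y_prime = y_prime, slope = slope,
    oi_axis_m = oi_axis_m, oi_other_m = oi_other_m,
    negative = oi_axis_m < 0 | oi_other_m < 0
  )
  class(out) <- c("tangent_decomposition", "data.frame")
  out
}

#' @export
print.tangent_decomposition <- function(x, ...) {
  cat("<tangent_decomposition> (intercepts at x = 1 and x = 0)\n")
  print.data.frame(x, ...)
  if (any(x$negative))
    cat("note: negative partial differential OI(s); interpret as the change of\n",
        "the mixture's OI per added lnOAV unit, not as a perceived intensity\n",
        sep = "")
  invisible(x)
}

#' Predict a binary mixture's odor intensity
#'
#' Runs the full chain: form the mixing proportion x from the pair of
#' lnOAVs using the curve's axis orientation, take the tangent
#' decomposition at x, and combine the partial differential odor
#' intensities with the lnOAVs:
#' OI = OI_a,m * lnOAV_a + OI_b,m * lnOAV_b. Because the tangency point
#' sits on the fitted curve, this equals (lnOAV_a + lnOAV_b) * f(x).
#'
#' @param curve an [interaction_curve()]; its `axis_component` decides
#'   which argument supplies the horizontal coordinate.
#' @param ln_oav_a,ln_oav_b lnOAV of components a and b, in the order of
#'   `curve$components`. Both must be > 0 (above threshold). Vectorized.
#' @return an object of class `"prediction_result"`: a data.frame with
#'   columns `x`, `oi_m`, `oi_a_m`, `oi_b_m`, `predicted_oi`, `negative`.
#' @export
#' @examples
#' te <- interaction_curve(c(1.73, -2.13, 1.40),
#'                         components = c("toluene", "ethylbenzene"),
#'                         axis_component = "ethylbenzene")
#' predict_oi(te, ln_oav_a = 3.36, ln_oav_b = 3.54)  # 5.3
predict_oi <- function(curve, ln_oav_a, ln_oav_b) {
  if (!inherits(curve, "interaction_curve"))
    abort_invalid("'curve' must be an interaction_curve")
  if (length(ln_oav_a) != length(ln_oav_b))
    abort_invalid("'ln_oav_a' and 'ln_oav_b' must have the same length")
  if (any(!is.finite(ln_oav_a)) || any(!is.finite(ln_oav_b)))
    abort_invalid("lnOAV values must be finite")
  if (any(ln_oav_a <= 0) || any(ln_oav_b <= 0))
    abort_subthreshold("both components must be above threshold (lnOAV > 0)")
  axis_is_a <- curve$axis_component == curve$components[1L]
  total <- ln_oav_a + ln_oav_b
  x <- (if (axis_is_a) ln_oav_a else ln_oav_b) / total
  dec <- tangent_decompose(curve, x)
  oi_a_m <- if (axis_is_a) dec$oi_axis_m else dec$oi_other_m
  oi_b_m <- if (axis_is_a) dec$oi_other_m else dec$oi_axis_m
  out <- data.frame(
    x = x, oi_m = dec$y_prime, oi_a_m = oi_a_m, oi_b_m = oi_b_m,
    predicted_oi = oi_a_m * ln_oav_a + oi_b_m * ln_oav_b,
    negative = dec$negative
  )
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result>\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Fit an interaction model to a table of binary mixture observations
#'
#' Convenience wrapper: transforms the observations ([pde_transform()]),
#' fits the requested family ([fit_curve()]; `family = "auto"` ranks all
#' families with [compare_families()] and keeps the best), or pools the
#' points into the symmetric curve ([fit_extended()]).
#'
#' @param mixtures data.frame of observations (see [pde_transform()]).
#' @param axis_component horizontal-axis component (`"a"`, `"b"`, or an
#'   odorant name); irrelevant for `extended = TRUE`.
#' @param family curve family, or `"auto"`.
#' @param extended fit the symmetric pooled curve instead.
#' @param label optional mixture label.
#' @return an [interaction_curve()].
#' @export
fit_pde <- function(mixtures, axis_component = "a", family = "quadratic",
                    extended = FALSE, label = NULL) {
  tr <- pde_transform(mixtures, axis_component)
  comps <- if (all(c("odorant_a", "odorant_b") %in% names(tr)))
    c(tr$odorant_a[1L], tr$odorant_b[1L]) else c("a", "b")
  axis_name <- if (resolve_axis(tr, axis_component) == "a") comps[1L] else comps[2L]
  if (is.null(label) && !identical(comps, c("a", "b")))
    label <- paste(comps, collapse = "+")
  if (extended) return(fit_extended(tr$x, tr$oi_m,
                                    label = if (is.null(label)) "extended" else label))
  if (identical(family, "auto")) {
    fits <- compare_families(tr$x, tr$oi_m, components = comps,
                             axis_component = axis_name, label = label)
    fits[[1L]]
  } else {
    fit_curve(tr$x, tr$oi_m, family = family, components = comps,
              axis_component = axis_name, label = label)
  }
}
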