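# Classical reference models for binary odor mixtures, used as baselines:
# the vector (U) model, the strongest-component model and the additivity
# model, plus the predictive-coefficient metric used to score them. Unlike
# the tangent-intercept model these work from the odor intensities of the
# unmixed components, not from chemical concentrations.

#' Strongest-component model
#'
#' The mixture smells as strong as its strongest component:
#' OI = max(OI_a, OI_b).
#'
#' @param oi_a,oi_b odor intensities of the unmixed components (>= 0).
#'   Vectorized.
#' @return predicted mixture odor intensity.
#' @export
#' @examples
#' predict_sc(4.3, 3.1)  # 4.3
predict_sc <- function(oi_a, oi_b) {
  check_oi_pair(oi_a, oi_b)
  pmax(oi_a, oi_b)
}

#' Additivity model
#'
#' Component intensities add: OI = OI_a + OI_b. Typically overpredicts —
#' mixtures of similar odorants show partial suppression.
#'
#' @inheritParams predict_sc
#' @return predicted mixture odor intensity.
#' @export
#' @examples
#' predict_add(5.2, 4.5)  # 9.7
predict_add <- function(oi_a, oi_b) {
  check_oi_pair(oi_a, oi_b)
  oi_a + oi_b
}

check_oi_pair <- function(oi_a, oi_b) {
  if (!is.numeric(oi_a) || !is.numeric(oi_b) ||
      any(!is.finite(oi_a)) || any(!is.finite(oi_b)))
    abort_invalid("odor intensities must be finite numbers")
  if (any(oi_a < 0) || any(oi_b < 0))
    abort_invalid("odor intensities must be non-negative")
  invisible(TRUE)
}

#' Estimate the vector-model interaction angle
#'
#' The vector (U) model represents the two components as vectors of length
#' OI_a and OI_b meeting at angle alpha, the mixture intensity being the
#' magnitude of their sum: OI_mix^2 = OI_a^2 + OI_b^2 + 2 OI_a OI_b cos(alpha).
#' Solving for the interaction parameter:
#' cos(alpha) = (OI_mix^2 - OI_a^2 - OI_b^2) / (2 OI_a OI_b).
#' Estimates outside \[-1, 1\] (possible with inconsistent triples) are
#' returned unclamped with `in_range = FALSE`.
#'
#' @param oi_a,oi_b odor intensities of the unmixed components (> 0).
#' @param oi_mix measured odor intensity of the mixture (>= 0). Vectorized.
#' @return an object of class `"vector_model_params"`: a data.frame with
#'   columns `cos_alpha` and `in_range`.
#' @export
#' @examples
#' estimate_cos_alpha(3, 4, 5)  # cos(alpha) = 0, a right angle
estimate_cos_alpha <- function(oi_a, oi_b, oi_mix) {
  check_oi_pair(oi_a, oi_b)
  if (any(oi_a == 0) || any(oi_b == 0))
    stop_odormix("odormix_undefined_parameter",
                 "cos(alpha) is undefined when a component's OI is 0")
  if (any(!is.finite(oi_mix)) || any(oi_mix < 0))
    abort_invalid("'oi_mix' must be non-negative and finite")
  ca <- (oi_mix^2 - oi_a^2 - oi_b^2) / (2 * oi_a * oi_b)
  out <- data.frame(cos_alpha = ca, in_range = abs(ca) <= 1)
  class(out) <- c("vector_model_params", "data.frame")
  out
}

#' Vector (U) model prediction
#'
#' @inheritParams predict_sc
#' @param cos_alpha interaction parameter, from [estimate_cos_alpha()] (a
#'   `vector_model_params` object or a plain number).
#' @return predicted mixture odor intensity, the magnitude of the vector
#'   sum.
#' @export
#' @examples
#' predict_u(3, 4, 0)  # 5
predict_u <- function(oi_a, oi_b, cos_alpha) {
  check_oi_pair(oi_a, oi_b)
  if (inherits(cos_alpha, "vector_model_params")) cos_alpha <- cos_alpha$cos_alpha
  rad <- oi_a^2 + oi_b^2 + 2 * oi_a * oi_b * cos_alpha
  if (any(rad < -1e-12))
    stop_odormix("odormix_invalid_parameter",
                 "negative radicand: cos(alpha) too antagonistic for these intensities")
  sqrt(pmax(rad, 0))
}

#' Predictive coefficient of a model
#'
#' The per-sample predictive coefficient is the ratio of predicted to
#' measured odor intensity; a model is scored by the arithmetic mean of
#' these ratios, with 1.0 meaning predicted and measured agree on average.
#'
#' @param predicted numeric vector of model predictions.
#' @param measured numeric vector of panel-measured intensities (> 0).
#' @return a list with `ratios` (per-sample) and `mean`.
#' @export
#' @examples
#' predictive_coefficient(c(2, 4), c(4, 2))  # ratios 0.5 and 2, mean 1.25
predictive_coefficient <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    abort_invalid("'predicted' and 'measured' must have the same length")
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured <= 0))
    abort_invalid("'measured' intensities must be strictly positive")
  r <- predicted / measured
  list(ratios = r, mean = mean(r))
}

#' Score all comparison models on a set of mixture samples
#'
#' For each sample (a triple of unmixed-component OIs and the measured
#' mixture OI) computes the strongest-component, additivity and vector (U)
#' predictions plus, optionally, tangent-intercept model predictions, and
#' the per-model mean predictive coefficient.
#'
#' The U model needs cos(alpha), which is itself estimated from measured
#' triples; `cos_alpha_mode` controls how: `"mixture_mean"` (default)
#' averages the per-sample estimates within each `mixture` group,
#' `"per_sample"` uses each sample's own estimate (which reproduces the
#' measured mixture OI exactly), and `"fixed"` uses `cos_alpha_fixed`
#' everywhere.
#'
#' @param samples data.frame with columns `oi_a`, `oi_b`, `oi_mix` and
#'   optionally `mixture` (grouping), `ln_oav_a`, `ln_oav_b`.
#' @param curve optional [interaction_curve()]; when given together with
#'   lnOAV columns, a `pde` prediction column is added via [predict_oi()].
#' @param cos_alpha_mode `"mixture_mean"`, `"per_sample"` or `"fixed"`.
#' @param cos_alpha_fixed value used when `cos_alpha_mode = "fixed"`.
#' @return a list with `table` (per-sample predictions and ratios) and
#'   `mean_predictive_coefficient` (named vector, one entry per model).
#' @export
compare_models <- function(samples, curve = NULL,
                           cos_alpha_mode = c("mixture_mean", "per_sample", "fixed"),
                           cos_alpha_fixed = NULL) {
  cos_alpha_mode <- match.arg(cos_alpha_mode)
  samples <- as.data.frame(samples)
  need <- c("oi_a", "oi_b", "oi_mix")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    abort_invalid(paste0("samples need column(s): ", paste(miss, collapse = ", ")))

  ca <- estimate_cos_alpha(samples$oi_a, samples$oi_b, samples$oi_mix)$cos_alpha
  ca_used <- switch(cos_alpha_mode,
    per_sample = ca,
    fixed = {
      if (!is_scalar_number(cos_alpha_fixed))
        abort_invalid("'cos_alpha_fixed' must be a number when mode is 'fixed'")
      rep(cos_alpha_fixed, nrow(samples))
    },
    mixture_mean = {
      grp <- if ("mixture" %in% names(samples)) samples$mixture
             else rep("all", nrow(samples))
      stats::ave(ca, grp, FUN = mean)
    }
  )

  out <- samples
  out$cos_alpha <- ca_used
  out$u <- predict_u(samples$oi_a, samples$oi_b, ca_used)
  out$sc <- predict_sc(samples$oi_a, samples$oi_b)
  out$add <- predict_add(samples$oi_a, samples$oi_b)
  models <- c("u", "sc", "add")
  if (!is.null(curve)) {
    if (!all(c("ln_oav_a", "ln_oav_b") %in% names(samples)))
      abort_invalid("tangent-intercept predictions need ln_oav_a/ln_oav_b columns")
    out$pde <- predict_oi(curve, samples$ln_oav_a, samples$ln_oav_b)$predicted_oi
    models <- c("pde", models)
  }
  mpc <- vapply(models, function(m)
    predictive_coefficient(out[[m]], out$oi_mix)$mean, numeric(1))
  for (m in models) out[[paste0("ratio_", m)]] <- out[[m]] / out$oi_mix
  list(table = out, mean_predictive_coefficient = mpc)
}
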