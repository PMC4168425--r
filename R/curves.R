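# Interaction-curve fitting in transformed (mixing proportion, averaged OI)
# space. The curve family of record is the quadratic polynomial -- binary
# aromatic mixtures trace an asymmetric "U" -- but the classical candidate
# families used for model screening are all available, each with a closed
# form for its value and first derivative so tangent lines are analytic.

CURVE_FAMILIES <- c("quadratic", "cubic", "logarithmic", "exponential",
                    "power", "logistic")

family_n_coef <- c(quadratic = 3L, cubic = 4L, logarithmic = 2L,
                   exponential = 2L, power = 2L, logistic = 3L)

family_coef_names <- list(
  quadratic   = c("a2", "a1", "a0"),          # y = a2 x^2 + a1 x + a0
  cubic       = c("a3", "a2", "a1", "a0"),    # y = a3 x^3 + ... + a0
  logarithmic = c("b0", "b1"),                # y = b0 + b1 ln x
  exponential = c("b0", "b1"),                # y = b0 exp(b1 x)
  power       = c("b0", "b1"),                # y = b0 x^b1
  logistic    = c("L", "k", "x0")             # y = L / (1 + exp(-k (x - x0)))
)

#' Construct an interaction curve from known coefficients
#'
#' An interaction curve is a function y = f(x) in transformed space, where
#' x is one component's share of the mixture's total lnOAV and y is the
#' averaged odor intensity OI_m = OI / (lnOAV_a + lnOAV_b). Curves are
#' usually produced by [fit_curve()] or [fit_extended()]; this constructor
#' builds one from published or otherwise pre-specified coefficients.
#'
#' The horizontal axis is tied to a specific component: `axis_component`
#' names which of `components` supplies x. Orientation is never inferred
#' from data — mirroring the axis (x -> 1 - x) changes every asymmetric
#' fit, so it must be stated.
#'
#' @param coefficients numeric vector, ordered as documented for the
#'   family (quadratic: `a2, a1, a0` for y = a2 x^2 + a1 x + a0).
#' @param family one of `"quadratic"`, `"cubic"`, `"logarithmic"`,
#'   `"exponential"`, `"power"`, `"logistic"`.
#' @param components length-2 character vector naming components a and b
#'   (in that order); defaults to `c("a", "b")`.
#' @param axis_component which component's mixing proportion is the
#'   horizontal coordinate; must be one of `components`. Default: the first.
#' @param label optional mixture label.
#' @param r_squared,n_points optional fit metadata.
#' @param symmetric logical; `TRUE` for curves constrained to be symmetric
#'   about x = 0.5 (quadratic with a1 = -a2).
#' @param fit optional underlying model object ([stats::lm]/[stats::nls]).
#' @return an object of class `"interaction_curve"`.
#' @seealso [curve_value()], [tangent_decompose()], [predict_oi()]
#' @export
#' @examples
#' # a published benzene+toluene curve, benzene on the horizontal axis
#' bt <- interaction_curve(c(1.93, -2.09, 1.39),
#'                         components = c("benzene", "toluene"),
#'                         axis_component = "benzene", label = "B+T")
#' curve_value(bt, 0.6)  # 0.83
interaction_curve <- function(coefficients, family = "quadratic",
                              components = c("a", "b"),
                              axis_component = components[1L],
                              label = NULL, r_squared = NA_real_,
                              n_points = NA_integer_, symmetric = FALSE,
                              fit = NULL) {
  family <- match.arg(family, CURVE_FAMILIES)
  k <- family_n_coef[[family]]
  if (!is.numeric(coefficients) || length(coefficients) != k)
    abort_invalid(sprintf("the %s family needs exactly %d coefficients", family, k))
  if (length(components) != 2L || anyDuplicated(components))
    abort_invalid("'components' must be two distinct names")
  if (!axis_component %in% components)
    abort_invalid("'axis_component' must be one of 'components'")
  coefficients <- stats::setNames(as.numeric(coefficients),
                                  family_coef_names[[family]])
  if (symmetric) {
    if (family != "quadratic")
      abort_invalid("symmetric curves are quadratic")
    if (abs(coefficients["a1"] + coefficients["a2"]) > 1e-8)
      abort_invalid("a symmetric quadratic requires a1 = -a2 (axis of symmetry x = 0.5)")
  }
  structure(
    list(label = label, family = family, coefficients = coefficients,
         components = components, axis_component = axis_component,
         r_squared = r_squared, n_points = n_points,
         symmetric = isTRUE(symmetric), fit = fit),
    class = "interaction_curve"
  )
}

#' @export
print.interaction_curve <- function(x, ...) {
  cat("<interaction_curve>", if (!is.null(x$label)) paste0(" ", x$label), "\n",
      "  family: ", x$family, if (x$symmetric) " (symmetric about x = 0.5)", "\n",
      "  axis (x): proportion of ", x$axis_component,
      "  [components: ", paste(x$components, collapse = " + "), "]\n",
      "  coefficients: ",
      paste(names(x$coefficients), format(x$coefficients, digits = 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  if (!is.na(x$r_squared))
    cat("  R^2 = ", format(x$r_squared, digits = 4),
        " (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Evaluate an interaction curve or its derivative
#'
#' Both use the closed form of the family, so tangent lines are analytic
#' rather than numeric.
#'
#' @param curve an [interaction_curve()].
#' @param x numeric vector of mixing proportions.
#' @return numeric vector of curve values (`curve_value`) or first
#'   derivatives (`curve_slope`).
#' @export
curve_value <- function(curve, x) {
  co <- curve$coefficients
  switch(curve$family,
    quadratic   = co[["a2"]] * x^2 + co[["a1"]] * x + co[["a0"]],
    cubic       = co[["a3"]] * x^3 + co[["a2"]] * x^2 + co[["a1"]] * x + co[["a0"]],
    logarithmic = co[["b0"]] + co[["b1"]] * log(x),
    exponential = co[["b0"]] * exp(co[["b1"]] * x),
    power       = co[["b0"]] * x^co[["b1"]],
    logistic    = co[["L"]] / (1 + exp(-co[["k"]] * (x - co[["x0"]])))
  )
}

#' @rdname curve_value
#' @export
curve_slope <- function(curve, x) {
  co <- curve$coefficients
  switch(curve$family,
    quadratic   = 2 * co[["a2"]] * x + co[["a1"]],
    cubic       = 3 * co[["a3"]] * x^2 + 2 * co[["a2"]] * x + co[["a1"]],
    logarithmic = co[["b1"]] / x,
    exponential = co[["b0"]] * co[["b1"]] * exp(co[["b1"]] * x),
    power       = co[["b0"]] * co[["b1"]] * x^(co[["b1"]] - 1),
    logistic    = {
      e <- exp(-co[["k"]] * (x - co[["x0"]]))
      co[["L"]] * co[["k"]] * e / (1 + e)^2
    }
  )
}

# least-squares fit of one family; returns list(coefficients, fit or NULL)
fit_family <- function(x, y, family) {
  df <- data.frame(x = x, y = y)
  if (family %in% c("logarithmic", "power") && any(x <= 0))
    abort_domain(sprintf("the %s family requires x > 0", family))
  switch(family,
    quadratic = {
      fit <- stats::lm(y ~ x + I(x^2), data = df)
      co <- stats::coef(fit)
      if (anyNA(co)) abort_degenerate("rank-deficient design for quadratic fit")
      list(coefficients = c(co[[3L]], co[[2L]], co[[1L]]), fit = fit)
    },
    cubic = {
      fit <- stats::lm(y ~ x + I(x^2) + I(x^3), data = df)
      co <- stats::coef(fit)
      if (anyNA(co)) abort_degenerate("rank-deficient design for cubic fit")
      list(coefficients = c(co[[4L]], co[[3L]], co[[2L]], co[[1L]]), fit = fit)
    },
    logarithmic = {
      fit <- stats::lm(y ~ log(x), data = df)
      co <- stats::coef(fit)
      if (anyNA(co)) abort_degenerate("rank-deficient design for logarithmic fit")
      list(coefficients = c(co[[1L]], co[[2L]]), fit = fit)
    },
    exponential = fit_nls(df, y ~ b0 * exp(b1 * x), start_exponential(df)),
    power       = fit_nls(df, y ~ b0 * x^b1, start_power(df)),
    logistic    = fit_nls(df, y ~ L / (1 + exp(-k * (x - x0))), start_logistic(df))
  )
}

# data-driven starting values for the iterative families
start_exponential <- function(df) {
  if (all(df$y > 0)) {
    lf <- stats::lm(log(y) ~ x, data = df)
    list(b0 = exp(stats::coef(lf)[[1L]]), b1 = stats::coef(lf)[[2L]])
  } else list(b0 = mean(df$y), b1 = 0)
}

start_power <- function(df) {
  if (all(df$y > 0) && all(df$x > 0)) {
    lf <- stats::lm(log(y) ~ log(x), data = df)
    list(b0 = exp(stats::coef(lf)[[1L]]), b1 = stats::coef(lf)[[2L]])
  } else list(b0 = mean(df$y), b1 = 1)
}

start_logistic <- function(df) {
  list(L = max(df$y) * 1.05 + 1e-6, k = 1,
       x0 = stats::median(df$x))
}

fit_nls <- function(df, formula, start) {
  fit <- tryCatch(
    stats::nls(formula, data = df, start = start),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # Gauss-Newton failed to converge; retry with Levenberg-Marquardt
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(formula, data = df, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) e
    )
    if (inherits(fit, "error"))
      abort_fit(paste0("nonlinear fit did not converge: ",
                       conditionMessage(fit)))
    if (!isTRUE(fit$convInfo$isConv))
      abort_fit("nonlinear fit did not converge within 200 iterations")
  }
  co <- stats::coef(fit)
  list(coefficients = unname(co), fit = fit)
}

r_squared_about_mean <- function(y, fitted) {
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  if (sst > 0) 1 - sse / sst else as.numeric(sse <= .Machine$double.eps)
}

#' Fit an interaction curve to transformed mixture points
#'
#' Unweighted least squares of averaged odor intensity on mixing proportion.
#' Polynomial and logarithmic families are linear in their coefficients and
#' fitted by [stats::lm()]; exponential, power and logistic families are
#' fitted by [stats::nls()] (with a Levenberg-Marquardt fallback). For all
#' families the goodness of fit reported is R^2 = 1 - SSE/SST about the
#' mean of y.
#'
#' @param x mixing proportions (the `axis_component`'s lnOAV share).
#' @param y averaged odor intensities OI_m.
#' @param family curve family, default `"quadratic"`.
#' @param components,axis_component,label metadata stored on the curve;
#'   see [interaction_curve()].
#' @return an [interaction_curve()].
#' @export
#' @examples
#' x <- c(0.2, 0.5, 0.8)
#' fit_curve(x, 1.93 * x^2 - 2.09 * x + 1.39)  # exact interpolation
fit_curve <- function(x, y, family = "quadratic",
                      components = c("a", "b"),
                      axis_component = components[1L], label = NULL) {
  family <- match.arg(family, CURVE_FAMILIES)
  if (length(x) != length(y))
    abort_invalid("'x' and 'y' must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_invalid("'x' and 'y' must be finite")
  k <- family_n_coef[[family]]
  if (length(x) < k)
    abort_invalid(sprintf("the %s family needs at least %d points", family, k))
  if (length(unique(x)) < min(k, length(x)))
    abort_degenerate("too few distinct x values for this family")
  res <- fit_family(x, y, family)
  cv <- interaction_curve(res$coefficients, family = family,
                          components = components,
                          axis_component = axis_component, label = label,
                          n_points = length(x), fit = res$fit)
  cv$r_squared <- r_squared_about_mean(y, curve_value(cv, x))
  cv$data <- data.frame(x = x, y = y)
  cv
}

#' Fit and rank all applicable curve families
#'
#' Fits each candidate family to the same points and ranks them by R^2
#' (descending), breaking ties in favour of fewer parameters. Fits whose
#' R^2 differ by less than `tie_tol` count as tied: nested families (cubic
#' over quadratic) always gain a numerically trivial amount of R^2 from
#' their extra parameter, and only parsimony can separate fits of
#' practically identical quality. Families whose domain excludes the data
#' (logarithm or power with x <= 0) or whose iterative fit fails are
#' skipped with a warning.
#'
#' @inheritParams fit_curve
#' @param families candidate families to try.
#' @param tie_tol R^2 differences below this count as a tie; default 0.005
#'   (differences invisible at the 2-decimal reporting precision).
#' @return a list of [interaction_curve()]s, best first, with a summary
#'   data.frame attached as attribute `"ranking"`.
#' @export
compare_families <- function(x, y, families = CURVE_FAMILIES,
                             components = c("a", "b"),
                             axis_component = components[1L], label = NULL,
                             tie_tol = 0.005) {
  families <- match.arg(families, CURVE_FAMILIES, several.ok = TRUE)
  fits <- list()
  for (fam in families) {
    cv <- tryCatch(
      fit_curve(x, y, family = fam, components = components,
                axis_component = axis_component, label = label),
      odormix_error = function(e) {
        warning(sprintf("family '%s' skipped: %s", fam, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(cv)) fits[[fam]] <- cv
  }
  if (!length(fits)) abort_fit("no curve family could be fitted")
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  npar <- family_n_coef[names(fits)]
  # cluster fits whose R^2 are within tie_tol of the cluster's best, then
  # order within a cluster by parameter count (parsimony)
  ord0 <- order(-r2)
  grp <- integer(length(ord0))
  g <- 1L
  leader <- r2[ord0[1L]]
  for (k in seq_along(ord0)) {
    if (leader - r2[ord0[k]] > tie_tol) {
      g <- g + 1L
      leader <- r2[ord0[k]]
    }
    grp[k] <- g
  }
  ord <- ord0[order(grp, npar[ord0], -r2[ord0])]
  fits <- fits[ord]
  attr(fits, "ranking") <- data.frame(
    family = names(fits),
    r_squared = r2[ord],
    n_coefficients = as.integer(npar[ord]),
    row.names = NULL
  )
  fits
}

#' Fit the symmetric (extended) interaction curve
#'
#' Pooling several binary mixtures requires a curve that does not depend on
#' which component is placed on the horizontal axis, so the quadratic is
#' constrained to be symmetric about x = 0.5: y = a2 x^2 - a2 x + a0,
#' fitted by constrained least squares (a linear model in (x^2 - x)).
#' Mirroring the data (x -> 1 - x) leaves the fit unchanged.
#'
#' @param x pooled mixing proportions (any consistent orientation).
#' @param y pooled averaged odor intensities.
#' @param label optional label.
#' @return a symmetric quadratic [interaction_curve()].
#' @export
fit_extended <- function(x, y, label = "extended") {
  if (length(x) != length(y))
    abort_invalid("'x' and 'y' must have the same length")
  if (length(x) < 2L)
    abort_invalid("the symmetric quadratic needs at least 2 points")
  df <- data.frame(x = x, y = y, z = x^2 - x)
  if (length(unique(df$z)) < 2L)
    abort_degenerate("all points at the same |x - 0.5|; curvature not identifiable")
  fit <- stats::lm(y ~ z, data = df)
  a2 <- stats::coef(fit)[[2L]]
  a0 <- stats::coef(fit)[[1L]]
  cv <- interaction_curve(c(a2, -a2, a0), family = "quadratic",
                          label = label, symmetric = TRUE,
                          n_points = length(x), fit = fit)
  cv$r_squared <- r_squared_about_mean(y, curve_value(cv, x))
  cv$data <- df[c("x", "y")]
  cv
}

#' Prediction interval of a fitted interaction curve
#'
#' Standard ordinary-least-squares prediction interval for a new
#' observation on the curve's design (Student-t quantile at the stated
#' level), available for families fitted as linear models (quadratic,
#' cubic, logarithmic, and the symmetric quadratic).
#'
#' @param curve a curve from [fit_curve()] or [fit_extended()].
#' @param x_grid mixing proportions at which to evaluate the interval.
#' @param level interval level in (0, 1); default 0.90.
#' @return a data.frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
prediction_interval <- function(curve, x_grid, level = 0.90) {
  if (!inherits(curve, "interaction_curve"))
    abort_invalid("'curve' must be an interaction_curve")
  if (!is_scalar_number(level) || level <= 0 || level >= 1)
    abort_invalid("'level' must lie in (0, 1)")
  fit <- curve$fit
  if (is.null(fit) || !inherits(fit, "lm"))
    abort_invalid(
      "prediction intervals require a curve fitted as a linear model (quadratic, cubic, logarithmic or symmetric)")
  if (fit$df.residual < 1L)
    stop_odormix("odormix_interval_undefined",
                 "no residual degrees of freedom; the prediction interval is undefined")
  newdata <- data.frame(x = x_grid)
  if (curve$symmetric) newdata$z <- x_grid^2 - x_grid
  pi <- stats::predict(fit, newdata = newdata, interval = "prediction",
                       level = level)
  data.frame(x = x_grid, fit = pi[, "fit"], lower = pi[, "lwr"],
             upper = pi[, "upr"])
}
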