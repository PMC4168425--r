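# Seedable generator of olfactometry-style datasets with known ground
# truth. It emulates a sensory panel rating binary mixtures against the
# 1-butanol referencing scale: a true interaction curve fixes each
# sample's latent odor intensity, each assessor adds a constant personal
# bias plus per-rating noise, scores snap to the half-point grid and are
# clipped to the scale, and the panel mean becomes the observed OI.

default_lnoav_design <- function() {
  # 11 mixing proportions spanning the U-curve crossed with a low and a
  # high total lnOAV (panel studies run ~22 samples per mixture, totals
  # roughly 2-7)
  x <- seq(0.1, 0.9, length.out = 11)
  totals <- c(3, 6)
  do.call(rbind, lapply(totals, function(s)
    data.frame(ln_oav_a = x * s, ln_oav_b = (1 - x) * s)))
}

#' Configuration for the synthetic sensory-panel generator
#'
#' Defaults emulate the study conditions of a benzene-series olfactometry
#' panel: a symmetric true curve y = 2.36 x^2 - 2.36 x + 1.36, 22 design
#' pairs (11 mixing proportions at total lnOAV 3 and 6), 10 assessors,
#' per-assessor bias sd 0.2 and per-rating noise sd 0.3 (a repeat-rating
#' difference within 0.5 OIRS points is considered acceptable), half-point
#' score rounding, and clipping to the \[0, 8\] scale.
#'
#' @param true_curve an [interaction_curve()] or a length-3 numeric vector
#'   of quadratic coefficients (a2, a1, a0); x is component a's proportion.
#' @param lnoav_design data.frame with columns `ln_oav_a`, `ln_oav_b`, all
#'   strictly positive.
#' @param n_assessors panel size (>= 1).
#' @param assessor_bias_sd sd of each assessor's constant bias, OIRS units.
#' @param rating_noise_sd sd of per-rating noise, OIRS units.
#' @param round_to_half snap each score to the 0.5-point grid.
#' @param seed integer seed making the dataset reproducible.
#' @return a list of class `"synthetic_config"`.
#' @seealso [generate_mixture_dataset()]
#' @export
synthetic_config <- function(true_curve = c(2.36, -2.36, 1.36),
                             lnoav_design = default_lnoav_design(),
                             n_assessors = 10,
                             assessor_bias_sd = 0.2,
                             rating_noise_sd = 0.3,
                             round_to_half = TRUE,
                             seed = 1L) {
  if (is.numeric(true_curve))
    true_curve <- interaction_curve(true_curve, family = "quadratic")
  if (!inherits(true_curve, "interaction_curve"))
    abort_invalid("'true_curve' must be an interaction_curve or quadratic coefficients")
  lnoav_design <- as.data.frame(lnoav_design)
  if (!all(c("ln_oav_a", "ln_oav_b") %in% names(lnoav_design)))
    abort_invalid("'lnoav_design' needs columns ln_oav_a and ln_oav_b")
  if (any(lnoav_design$ln_oav_a <= 0) || any(lnoav_design$ln_oav_b <= 0))
    stop_odormix("odormix_config_error",
                 "all design pairs must be above threshold (lnOAV > 0)")
  if (!is_scalar_number(n_assessors) || n_assessors < 1)
    stop_odormix("odormix_config_error", "'n_assessors' must be >= 1")
  if (assessor_bias_sd < 0 || rating_noise_sd < 0)
    stop_odormix("odormix_config_error", "noise parameters must be >= 0")
  structure(
    list(true_curve = true_curve, lnoav_design = lnoav_design,
         n_assessors = as.integer(n_assessors),
         assessor_bias_sd = assessor_bias_sd,
         rating_noise_sd = rating_noise_sd,
         round_to_half = isTRUE(round_to_half), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic binary-mixture panel dataset
#'
#' For each design pair the latent truth is
#' OI = (lnOAV_a + lnOAV_b) * f_true(x) with x = lnOAV_a / total. Each
#' assessor's score is truth + personal bias + rating noise, optionally
#' snapped to the half-point grid, clipped to \[0, 8\]; the observed OI is
#' the panel mean. The same seed always yields the same dataset.
#'
#' @param config a [synthetic_config()].
#' @return a list with
#'   \describe{
#'     \item{mixtures}{data.frame `sample_id`, `odorant_a`, `odorant_b`,
#'       `ln_oav_a`, `ln_oav_b`, `oi` — ready for [fit_pde()].}
#'     \item{panel}{long data.frame of per-assessor scores
#'       (`sample_id`, `assessor_id`, `score`).}
#'     \item{truth}{list with the true curve coefficients, true per-sample
#'       OI and the config.}
#'   }
#' @export
#' @examples
#' d <- generate_mixture_dataset(synthetic_config(seed = 42))
#' fit_pde(d$mixtures, axis_component = "a")
generate_mixture_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    abort_invalid("'config' must come from synthetic_config()")
  des <- config$lnoav_design
  n <- nrow(des)
  total <- des$ln_oav_a + des$ln_oav_b
  x <- des$ln_oav_a / total
  true_oi <- total * curve_value(config$true_curve, x)

  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  bias <- stats::rnorm(config$n_assessors, 0, config$assessor_bias_sd)

  scores <- matrix(NA_real_, nrow = n, ncol = config$n_assessors)
  for (j in seq_len(config$n_assessors)) {
    s <- true_oi + bias[j] + stats::rnorm(n, 0, config$rating_noise_sd)
    if (config$round_to_half) s <- round(s * 2) / 2
    scores[, j] <- pmin(pmax(s, 0), OIRS_MAX)
  }

  sample_id <- sprintf("syn%02d", seq_len(n))
  mixtures <- data.frame(
    sample_id = sample_id, odorant_a = "a", odorant_b = "b",
    ln_oav_a = des$ln_oav_a, ln_oav_b = des$ln_oav_b,
    oi = rowMeans(scores)
  )
  panel <- data.frame(
    sample_id = rep(sample_id, times = config$n_assessors),
    assessor_id = rep(sprintf("A%02d", seq_len(config$n_assessors)), each = n),
    score = as.vector(scores)
  )
  list(
    mixtures = mixtures, panel = panel,
    truth = list(coefficients = config$true_curve$coefficients,
                 family = config$true_curve$family,
                 x = x, true_oi = true_oi, config = config)
  )
}

#' Generate a synthetic single-odorant calibration dataset
#'
#' Simulates the linear OI ~ lnOAV relation of an individual odorant:
#' oi = slope * ln_oav + intercept + Gaussian noise, clipped to the
#' \[0, 8\] OIRS range.
#'
#' @param slope,intercept true line parameters.
#' @param lnoav_grid lnOAV values at which samples are rated.
#' @param noise_sd Gaussian noise sd (>= 0), OIRS units.
#' @param seed integer seed.
#' @return data.frame with columns `ln_oav` and `oi`.
#' @export
#' @examples
#' d <- generate_individual_dataset(0.9, 0.4, seq(1, 6, length.out = 50),
#'                                  noise_sd = 0.1, seed = 7)
#' fit_individual(d$ln_oav, d$oi)
generate_individual_dataset <- function(slope, intercept, lnoav_grid,
                                        noise_sd = 0.1, seed = 1L) {
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    abort_invalid("'noise_sd' must be >= 0")
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  oi <- slope * lnoav_grid + intercept + stats::rnorm(length(lnoav_grid), 0, noise_sd)
  data.frame(ln_oav = lnoav_grid, oi = pmin(pmax(oi, 0), OIRS_MAX))
}

# preserve the caller's RNG state across seeded generation
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
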