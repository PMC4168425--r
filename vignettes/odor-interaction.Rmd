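---
title: "Modelling odor interaction in binary mixtures by the tangent-intercept method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling odor interaction in binary mixtures by the tangent-intercept method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odormix)
```

## The problem

Air with several odorants rarely smells as strong as the sum of its parts:
chemically similar odorants partially mask one another, and regulatory
limits on individual compounds say little about how intense the mixture
will smell. Panels of trained assessors can rate odor intensity (OI)
against a 1-butanol referencing scale, but panels are expensive, fatigue
quickly, and cannot sit next to an on-line gas detector. A model that maps
*measured chemical concentrations* of a binary mixture to its *perceived
odor intensity* lets instruments stand in for assessors.

odormix implements such a model for binary mixtures, built on an analogy
with partial molar volume analysis of liquid solutions, together with the
classical comparison models, the supporting psychophysics, and a synthetic
sensory-panel generator that makes the whole pipeline testable with known
ground truth.

## From concentrations to the model's coordinates

The dose scale is the **odor activity value** OAV = C / C~thr~, a sample's
concentration over the odorant's detection threshold, both in mg/m³
(`compute_oav()`, thresholds from forced-choice dilution series via
`threshold_from_panel()`). For an individual odorant, panel OI is linear in
ln OAV (`fit_individual()`); this linearity is the precondition for the
whole construction, because it makes lnOAV play the role that mole numbers
play for solution volumes.

For a binary mixture with components *a* and *b*:

* averaged intensity: OI~m~ = OI / (lnOAV~a~ + lnOAV~b~)
* mixing proportion: x~a~ = lnOAV~a~ / (lnOAV~a~ + lnOAV~b~)

`pde_transform()` applies this to a table of observations. Plotting OI~m~
against x~a~ over many mixing ratios and concentration levels traces an
asymmetric U-shaped curve y = f(x), fitted by unweighted least squares
(`fit_curve()`). The tangent line at a point (x′, y′) of that curve has
intercepts on the two vertical axes x = 1 and x = 0:

* OI~axis,m~ = (1 − x′)·f′(x′) + y′
* OI~other,m~ = −x′·f′(x′) + y′

These are the **partial differential odor intensities**
(`tangent_decompose()`): the change of the mixture's OI per unit lnOAV of
the corresponding component. A mixture's intensity is then predicted as

OI = OI~a,m~·lnOAV~a~ + OI~b,m~·lnOAV~b~,

which, because the tangency point lies on the curve, is algebraically equal
to (lnOAV~a~ + lnOAV~b~)·f(x) — an identity the test suite checks to
1e−10 (`predict_oi()` returns both forms' ingredients).

Near the ends of the mixing range one intercept is legitimately negative:
it is a marginal change, not a perceived intensity, so it is returned
unfloored with an advisory flag. Predictions for individual odorants
(`predict_individual()`), by contrast, are floored at zero.

## Design choices where the field leaves room

**Axis orientation is explicit.** For an asymmetric curve, mirroring the
horizontal axis (x → 1 − x) changes every coefficient, so each
`interaction_curve` records which odorant's proportion is x
(`axis_component`), and the CLI requires `--axis`. Reproducing the bundled
reference tables requires ethylbenzene on the axis for both of its
mixtures; orientation is never inferred from data. An orientation-consistency
property (predicting with the mirrored curve and swapped axis gives
identical results) is tested.

**Unweighted fitting.** Rating dispersion in raw OI units translates into
OI~m~ dispersion that shrinks with total lnOAV, but observed scatter around
the curve (±0.2) is treated as homoscedastic in transformed space; no
weighting scheme is imposed that the data cannot support.

**Curve families.** Besides the quadratic — the family of record — the
classical screening candidates are available with fixed functional forms:
cubic, logarithmic (b₀ + b₁ ln x), exponential (b₀·e^{b₁x}), power
(b₀·x^{b₁}) and logistic (L / (1 + e^{−k(x−x₀)})). Linear-in-coefficient
families go through `stats::lm()`, the rest through `stats::nls()` with
data-driven starts and a Levenberg–Marquardt fallback; a fit that has not
converged after 200 iterations is treated as failed and skipped from
comparisons with a warning. R² is defined as 1 − SSE/SST about the mean
for every family, linear or not.

**Ranking with a tie tolerance.** `compare_families()` ranks by R²
descending, but a nested family always gains a numerically trivial amount
of R² from its extra parameter, so fits whose R² differ by less than
0.005 — invisible at the two decimals at which R² is reported — count as
tied and the fewer-parameter family wins. Without this, the cubic would
"beat" the quadratic on every noisy quadratic dataset.

**Symmetric pooled curve.** Pooling several mixtures requires a curve
independent of axis orientation, so `fit_extended()` constrains the
quadratic to be symmetric about x = 0.5 (y = a₂x² − a₂x + a₀, a linear
model in x² − x). Mirror invariance is exact and tested.

**Prediction intervals.** `prediction_interval()` gives the standard OLS
interval for a new observation (Student-t, default level 0.90) on the
polynomial design; it is defined only for curves fitted as linear models
and with at least one residual degree of freedom. Empirical coverage is
checked by simulation (see below).

**Rounding for reports.** Printed tables round half away from zero
(`round_half_up()`): partial differential OIs to 2 decimals, predicted OI
to 1 decimal. Internal computation always keeps full precision.

**Sub-threshold components are rejected, not clamped.** lnOAV ≤ 0 makes
the mixing proportion meaningless; such rows raise a condition (the CLI
lists and skips them). The reference data contain none.

**Dilution averaging.** Thresholds use the arithmetic mean of recorded
dilution multiples by default; a geometric-mean option is exposed because
olfactometry standards often average dilution *steps* geometrically. The
1-butanol ladder follows its geometric rule, level k = 12·2^(k−1) ppm;
the scale's top level is commonly quoted as 1550 ppm although the doubling
rule gives 1536, so the rule, not the quoted endpoint, is implemented.

**Unit conversion.** mg/m³ ↔ ppm uses a configurable molar volume,
default 24.45 L/mol (25 °C, 1 atm). Published threshold tables often mix
conversion temperatures, so no single molar volume reproduces every
printed ppm value; thresholds are stored in mg/m³ and ppm is derived.

## The comparison models

The classical baselines work from the *unmixed components'* intensities:
strongest component (max), additivity (sum), and the vector (U) model
OI² = OI~a~² + OI~b~² + 2·OI~a~·OI~b~·cos α. The U model's functional
form is the standard vector-sum form from the mixture-perception
literature — adopted here as an external assumption, since only the
parameter cos α is defined operationally by the estimation data.
cos α estimated from one triple and fed back reproduces that triple
exactly (tested to 1e−10), so per-sample estimation is circular for
scoring; `compare_models()` therefore defaults to a per-mixture mean
cos α, with per-sample and user-fixed modes available. Models are scored
by the mean predictive coefficient (predicted/measured; 1.0 is perfect).

## The synthetic panel generator

`generate_mixture_dataset()` emulates an olfactometry campaign with known
truth: a true interaction curve (default the pooled symmetric quadratic
y = 2.36x² − 2.36x + 1.36), a design of 22 lnOAV pairs — 11 mixing
proportions from 0.1 to 0.9 crossed with total lnOAV 3 and 6, matching the
~2–7 totals and 22-samples-per-mixture layout of panel practice — and a
panel of 10 assessors. Each score is truth + a per-assessor constant bias
(sd 0.2) + per-rating noise (sd 0.3, consistent with a repeat-rating
difference within 0.5 OIRS points being acceptable), snapped to the
half-point grid and clipped to [0, 8]; the panel mean becomes the observed
OI. The generator is seeded and restores the caller's RNG state.

What it deliberately does **not** emulate: olfactory adaptation and
fatigue, assessor learning, correlated errors across samples rated in one
session, and odor-quality differences between the sample and the butanol
reference. Passing recovery tests therefore show the estimator works under
well-behaved panel noise, not that real panels are this well behaved.

## What the test suite establishes, and at what problem sizes

* the quadratic fit equals a brute-force normal-equations oracle to 1e−8
  on random instances of up to 10 points;
* the prediction identity OI ≡ (ΣlnOAV)·f(x) holds to 1e−10;
* cos α estimation and U prediction are exact inverses (1e−10);
* the symmetric fit is invariant under x → 1 − x;
* with the generator's default noise, all three fitted coefficients fall
  within ±0.3 of truth in ≥95% of 500 seeded replicates;
* the 90% prediction interval covers a new observation with empirical
  frequency inside [0.85, 0.95] over 2000 seeded replicates (noise
  sd 0.1);
* increasing rating noise (sd 0, 0.2, 0.5; 200 replicates each) never
  improves mean coefficient recovery;
* every recomputable cell of the bundled reference tables reproduces:
  all 10 predicted-OI cells at 1 decimal and all 30 strongest-component
  and additivity cells exactly. The printed tangent-intercept cells were
  produced from unrounded regression coefficients, so a few re-round one
  hundredth away when recomputed from the published (rounded)
  coefficients; `reproduce_tables()` reports per-cell match flags rather
  than asserting those cells.

## Limitations

Binary mixtures only: mixtures of three or more components need a prior
classification step and are out of scope. The model is empirical — fitted
per mixture (or pooled with the symmetry constraint) — and extrapolation
beyond the calibrated lnOAV range, or to odorants with dissimilar odor
quality, is untested. Both components must be above threshold. Prediction
intervals are available only for the linear-in-coefficient families.
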