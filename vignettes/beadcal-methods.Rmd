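---
title: "Standard-curve calibration methods in beadcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-curve calibration methods in beadcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadcal)
```

## The calibration problem

A multiplex bead immunoassay reports, per well and analyte, the median
fluorescence intensity (MFI) over the analyte's beads. Each plate carries
a serial dilution series of a reference sample with known concentrations
(standard wells) and blank wells containing only buffer. Calibration means
fitting a standard curve to the standards, then inverting it at each test
well's MFI. Because assay noise is strongly heteroscedastic on the natural
scale and roughly constant on the log scale, *everything* in beadcal — the
model, the residuals, the limits of quantification, the delta-method
algebra — lives in `(x, y) = (log10 concentration, log10 MFI)` space;
natural units appear only at the reporting boundary (`conc = 10^x̂`,
natural-scale CV).

## Models and their assumptions

Three response families are available, fitted by least squares under the
assumption of i.i.d. Gaussian noise on log10 MFI:

* **LL5**, `y = c + (d − c)/(1 + 10^{b(x−e)})^f`: sigmoid with lower/upper
  asymptotes `c < d` (log10 MFI), halfway point `e` (log10 concentration),
  slope `b`, and asymmetry `f > 0` allowing the two asymptotes to be
  approached at different rates.
* **LL4**: the LL5 with `f = 1`; symmetric, inflection exactly at `e`.
* **EXP**: `y = a0 + b x` with `a0 = log10(y0)` — appropriate when the
  dilution series never reaches the upper asymptote and the log–log
  relation is effectively linear. We read the exponential's printed form
  `y0·10^{xb}` multiplicatively (slope `b` per log10-concentration unit):
  `b` is a growth *rate*, and this reading makes EXP the linear model the
  other two degenerate to. The API makes the reading explicit by
  parameterizing on `(a0, b)` directly.

A deliberately documented convention: under this parameterization
`10^{b(x−e)} → 0` as `x → ∞`, so an increasing curve has **negative** `b`.
beadcal never flips the sign silently; summaries report `b` as fitted.

`fit_standard_curve()` tries the families sequentially (default LL5 →
LL4 → EXP) and returns the first that converges, recording every attempt
in `fallback_log`. Rationale: the five-parameter fit is preferred when the
data support it, but short series or one-sided designs often only support
the simpler shapes. Total failure is itself a value — a non-converged
`curve_fit` carrying the log — so batch pipelines never lose provenance to
an exception.

### Starting values and convergence

The optimizer is Levenberg–Marquardt (`minpack.lm::nlsLM`). Self-start
values: `c0 = min(y) − 0.05·range`, `d0 = max(y) + 0.05·range`, `e0` the
`x` whose response is closest to midrange (replaced by the intercept of a
logit-linearized regression when that lands inside the design), `b0` the
slope of that regression, `f0 = 1`. Convergence uses relative tolerances
`ftol = ptol = 1e-8` with at most 200 iterations; all three are
user-settable via `control`. Any optimizer reaching the same least-squares
optimum would be equally valid; the reported covariance is the standard
Gauss–Markov approximation at the optimum. A fit whose parameters land
outside the model's domain (`c ≥ d`, `f ≤ 0`) is treated as
non-convergence and triggers fallback.

## Blank-control treatments

`apply_background()` implements four treatments of the blank geometric
mean (GM):

* **ignore** — blanks unused; the curve's own lower asymptote absorbs the
  background.
* **subtract** — GM subtracted from every standard (and, in calibration,
  every test) MFI. Wells driven to `≤ 0` are excluded with reason
  `nonpositive-after-subtract`, since their log10 is undefined; exclusions
  are recorded on the fit, never silent.
* **include** — the GM is appended as an extra standard point at
  concentration `min(expected)/dilution factor`. The dilution factor is
  inferred as the median ratio of consecutive distinct concentrations
  (exact for a serial design) and can be overridden.
* **constraint** — the lower asymptote coefficient is fixed at
  `log10(GM)`; it leaves the free-parameter set, so the covariance loses a
  row/column and the coefficient is absent from t-tests.

Calibrated test wells receive exactly the treatment of the curve they are
read off (subtract subtracts; the other three leave test MFI untouched):
calibration must live in the same response space as the curve it inverts.

## Fit diagnostics

`fit_statistics()` reports R² and adjusted R² on log10 MFI, AIC under the
Gaussian likelihood with the residual variance counted as a parameter
(`n ln 2π + n ln(RSS/n) + n + 2(p+1)` — the same convention as R's
`AIC()` on a least-squares fit, stated explicitly so values are comparable
across implementations), and the Neill lack-of-fit p-value.

The Neill test partitions residual variation into pure error (within
groups of replicate design points) and lack of fit, and refers
`F = [SS_lof/(m−p)] / [SS_pe/(n−m)]` to `F(m−p, n−m)`. The grouping rule
is a design choice the test's name alone does not fix: beadcal groups by
identical expected concentration (replicated dilutions give pure error)
and reports an explicit `undefined` status when no group has replicates or
`m` falls outside `(p, n)`, rather than inventing a grouping.

## Limits of quantification

Three estimators, all reported in log10 units with natural-scale
convenience fields, always per plate-and-analyte fit (curve shape and
variability are plate-specific, so pooling limits across plates would
discard exactly the variability the plate's curve is meant to calibrate):

* **Derivative** (`loq_derivative`): the bend points of the curve — the
  extrema of the second derivative, found as roots of the analytic third
  derivative by sign-change bracketing on a grid plus `uniroot` polishing.
  For the LL4 the roots have the closed form `e ± log10(2 + √3)/|b|`,
  which the tests use as an oracle for the numeric path. Not applicable to
  EXP (third derivative identically zero).
* **Interval** (`loq_interval`): LLOQ is where the lower prediction bound
  of the curve crosses the upper confidence bound of `ĉ`; HLOQ symmetric
  with `d̂`. Bands use the t distribution on the residual df with
  `se_fit² = gᵀΣg`. If several crossings exist the one closest to `e` is
  taken (the conservative, interior choice); no sign change over the
  search range gives `not-estimable`.
* **Coefficient of variation** (`loq_cv`): over a dense grid, the
  delta-method SE of the inverse-predicted concentration at the fitted
  response is converted to a natural-scale CV via
  `CV = sqrt(exp((SE·ln10)²) − 1)`; the limits are the extreme grid points
  with CV at or below the cutoff (default 20%). If even the minimum CV
  exceeds the cutoff the status is `not-estimable` and the minimum CV is
  reported in the settings.

The SE of an inverse-predicted concentration (`concentration_se`) comes
from implicit differentiation of `f(x̂; θ) = y`: `∇_θ x̂ = −g(x̂)/f′(x̂)`.
By default only parameter uncertainty is propagated — the SE is
*conditional on the observed MFI* — with `include_response_error = TRUE`
adding `σ²/f′(x̂)²`. We expose this as a flag rather than deciding
silently because both conventions are defensible: the conditional SE
quantifies curve uncertainty alone and is the one the CV method uses by
default. Near an asymptote `f′ → 0` and the SE is reported as infinite
status, not as a huge number that could be mistaken for a valid estimate.

Grid and search choices: 1,000 points spanning the standard range extended
by one dilution step on each side (the dilution step being the median
log10 spacing of the design). The extension lets limits fall slightly
outside the design, as they legitimately can; the resolution only affects
bracketing, since roots are polished to `1e-12`.

## Outliers, flagging and reliability

Standardized residuals are raw residuals over the fit's residual SD;
`get_outliers()` returns all and only the used points beyond the cutoff
(default 2, configurable). When a fit is numerically exact (σ below 1e-8)
standardized residuals are reported as zero — a noise/noise ratio carries
no information. The workflow is deliberately *not* auto-iterative: the
package detects, the analyst flags (`flag_and_refit()`, which preserves
both fits and keeps flagged points visible as empty circles in plots), and
any new exceedances after the refit are reported without being acted on.
One detect–flag–refit cycle reflects how plates are actually reviewed;
automated recursive trimming can chase its own tail on small designs.

`intra_icc()` computes Shrout–Fleiss intraclass correlations from ANOVA
mean squares (one-/two-way, consistency/agreement, single/average) with
F-based confidence intervals; all variants are exposed and none is
privileged, since the appropriate index depends on the operator design.
Negative ANOVA estimates are reported clipped at zero with an explicit
status, keeping the raw value alongside.

## Raw-file import

The fluorescence-type xPONENT 3.1 export is a sectioned CSV: header
metadata, then blocks opened by a `DataType:` line. The parser accepts any
block vocabulary generically, sniffs comma/semicolon delimiters, tolerates
a BOM, and collects malformed lines with their line numbers instead of
dropping them. Expected concentrations are never taken from the raw export
(instrument software does not carry them reliably); they are joined from a
dilution map (top concentration + factor, or an explicit table) in
`data_selection()`, which partitions wells by role patterns, errs on
colliding patterns and warns when no standards match. The shipped example
file `xponent_synthetic.csv` is synthetic, generated by this package in
that layout.

## The synthetic-plate generator

`generate_plate()` emulates the standard-curve portion of a real plate: a
16-point 1:2 dilution series with the top dilution duplicated (17 designed
points), two blank wells, 4PL truth, and Gaussian noise on log10 MFI.
Four presets mirror common pathologies: a clean plate; 7 missing points
(the most dilute wells, as below-detection dropouts usually are); missing
points plus one injected outlier; and two injected outliers. Outliers are
generated by doubling the noise SD of the affected wells — they are
*probabilistically*, not certainly, extreme, which matters when
interpreting detection tests (see below).

Defaults are fixture choices, chosen once to resemble a realistic cytokine
curve and documented here: truth `b = −1.2, c = 1.1, d = 3.2, e = 0.9`,
top concentration 10⁴ (spanning ~4.5 decades, with `e` mid-range), noise
SD 0.05 (≈ 12% CV on natural-scale MFI), blanks lognormal around `10^c`
with SD 0.05 so the blank GM sits at the lower asymptote, as the
subtract/constraint heuristics expect. A single seed drives the whole
plate.

What the generator does *not* emulate: bead-count-dependent MFI precision,
plate-position effects, carryover/cross-reactivity between analytes, and
inter-plate drift. Passing tests therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to every failure
mode of real assays.

## Numerical and testing notes

* Analytic derivatives (orders 1–3) and parameter gradients are obtained
  by symbolic differentiation of the model expression, cross-checked
  against central finite differences and, for the LL4 bend points, the
  closed form.
* The simulation problem sizes used by the test suite and the acceptance
  script — 200 plates for parameter recovery/CI coverage, 500 replicates
  for the lack-of-fit type-I error, 2,000 parameter draws for the
  bootstrap check of the delta method — were chosen to give stable Monte
  Carlo estimates at the tolerances being checked while keeping a full run
  in the tens of seconds.
* Because outliers are injected by inflating noise SD 2×, a plate with two
  injected outliers yields at least one |standardized residual| > 2 in
  slightly under half of replicates — per-well, injected wells are flagged
  an order of magnitude more often than clean wells, and the tests assert
  that contrast (injected-well flag rate > 3× clean-well rate) rather than
  a per-plate majority, which the 2× construction does not mathematically
  guarantee.
* The four-analyte toy workflow in the acceptance material regenerates the
  scenarios from this package's own seeded generator. Published
  summary-table values for that workflow depend on one specific historical
  realization of the simulated plates (whose seed and noise draws were
  never published), so value-level agreement with that table is not
  reproducible from scratch; the structural behavior (points excluded by
  subtraction, outlier flagging, refit bookkeeping) is.

## Known limitations

Weighted or robust regression is not offered (the log10 transform is the
variance stabilizer); limits of detection from blank distributions are out
of scope; the importer targets xPONENT 3.1's layout only; and the
exponential model, being linear in log space, supports neither the
derivative nor the interval LOQ method (both report `not-applicable`).
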