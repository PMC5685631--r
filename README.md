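# beadcal

Calibration and quality control for multiplex bead-based immunoassays.

Multiplex bead panels (e.g. Luminex xMAP) report a median fluorescence
intensity (MFI) per analyte per well. To turn the MFI of a test sample into
a concentration, every plate carries serial dilutions of a reference sample
(the *standard curve*) and blank wells estimating background signal.
`beadcal` implements that calibration workflow end to end for analysts
processing such plates in R:

* **Standard-curve fitting** on log10-transformed data by nonlinear least
  squares, trying the 5-parameter log-logistic, 4-parameter log-logistic
  and exponential-growth models sequentially until one converges, with the
  attempt history kept on the fit.
* **Four blank-control treatments**: ignore, subtract, include-as-a-point,
  or constrain the lower asymptote to the blank geometric mean.
* **Three limits-of-quantification (LOQ) estimators**: derivative (bend
  points of the curve), interval (prediction band vs asymptote confidence
  bounds) and coefficient of variation (delta-method SE of the
  inverse-predicted concentration).
* **Inverse prediction** of test-sample concentrations with delta-method
  standard errors, CVs and in/out-of-LOQ status.
* **QA/QC**: standardized-residual outlier detection, flag-and-refit with
  full provenance, lack-of-fit (Neill) testing, intraclass correlation
  across operators/runs, and a report bundle with curves, residual and QQ
  plots.
* **Raw data import** for sectioned xPONENT 3.1 CSV exports (fluorescence
  and bead layouts) and role-based partitioning of wells into standards,
  blanks, controls and tests.
* A **seeded synthetic-plate generator** so every step can be exercised
  (and was tested) without instrument data.

## The model

All fitting happens in `(x, y) = (log10 concentration, log10 MFI)` space.
The five-parameter log-logistic curve is parameterized as

    y = c + (d - c) / (1 + 10^(b (x - e)))^f

where `c` and `d` are the lower and upper asymptotes (log10 MFI), `e` is
the log10 concentration at the halfway response, `b` is the slope around
`e` and `f > 0` the asymmetry. Setting `f = 1` gives the 4PL. Note the
sign convention: because `10^(b (x - e)) -> 0` as `x -> Inf`, an
*increasing* curve has `b < 0`. The exponential model is the line
`y = a0 + b x` with `a0 = log10(y0)`, `y0` being the response with no
analyte.

Concentration uncertainty uses the delta method: for a response `y`, the
inverse estimate `x̂` has gradient `-g(x̂)/f'(x̂)` with respect to the curve
parameters (`g` the parameter gradient), and its CV on the natural scale is
`sqrt(exp((SE ln 10)^2) - 1)`.

## Worked example

```r
library(beadcal)

# a realistic synthetic plate: 16 two-fold dilutions, duplicated top,
# two blanks, Gaussian noise (sd 0.05) on log10 MFI
plate <- generate_plate(scenario_presets()$analyte1, seed = 42, n_tests = 5)

fit <- fit_standard_curve(plate$standards, plate$blanks,
                          bkg_method = "subtract")
glance(fit)[, c("model_id", "n_used", "r2", "aic", "neill_p")]
#> # A tibble: 1 × 5
#>   model_id n_used    r2   aic neill_p
#>   <chr>     <int> <dbl> <dbl>   <dbl>
#> 1 LL5          17 0.998 -45.8   0.718

loq_derivative(fit)
#> <loq_estimate derivative> status: ok
#>   LLOQ 0.1883  HLOQ 1.1470  dynamic range 0.9587 (log10 units)

cal <- batch_calibrate(fit, loq_derivative(fit), plate$tests)
cal[, c("well", "mfi", "x_hat", "se_x", "cv", "status")]
#> # A tibble: 5 × 6
#>   well     mfi   x_hat    se_x        cv status
#>   <chr>  <dbl>   <dbl>   <dbl>     <dbl> <chr>
#> 3 B10    505.   1.26    0.0293  6.75e- 2 above-hloq
#> 5 B12     18.8  0.0980  0.0448  1.03e- 1 below-lloq
#> # ...
```

Here the LL5 model converged first and used all 17 standard points
(`n_used`); `r2` and `aic` are computed on log10 MFI, and `neill_p` is the
lack-of-fit p-value from replicated dilutions (0.72: no evidence of
misfit). The derivative-method LOQ brackets the near-linear stretch of the
curve, and each calibrated well reports its log10 concentration `x_hat`,
delta-method `se_x`, natural-scale `cv`, and whether it fell inside the
quantifiable range.

Raw xPONENT exports enter through the importer:

```r
raw <- lum_import(system.file("extdata", "xponent_synthetic.csv",
                              package = "beadcal"), "fluorescence")
long <- tidy_fluorescence(raw, block = "Median")
sel <- data_selection(long, dilution = list(top = 1e4, factor = 2))
```

(`xponent_synthetic.csv` is a synthetic file in the xPONENT 3.1 sectioned
layout, shipped for examples and tests.)

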