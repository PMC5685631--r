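new_loq_estimate <- function(method, lloq = NA_real_, hloq = NA_real_,
                             status = "ok", settings = list()) {
  structure(
    list(method = method, lloq = lloq, hloq = hloq,
         dynamic_range = if (status == "ok") hloq - lloq else NA_real_,
         status = status, settings = settings),
    class = "loq_estimate"
  )
}

#' @export
print.loq_estimate <- function(x, ...) {
  cat("<loq_estimate ", x$method, "> status: ", x$status, "\n", sep = "")
  if (x$status == "ok") {
    cat(sprintf("  LLOQ %.4f  HLOQ %.4f  dynamic range %.4f (log10 units)\n",
                x$lloq, x$hloq, x$dynamic_range))
  }
  invisible(x)
}

# free-parameter gradient consistent with the fit's covariance
free_gradient <- function(fit, x) {
  g <- param_gradient(fit$model, x)
  g[, fit$free, drop = FALSE]
}

se_fit_at <- function(fit, x) {
  g <- free_gradient(fit, x)
  sqrt(pmax(rowSums((g %*% fit$vcov) * g), 0))
}

# log10 spacing between consecutive dilutions; grid-extension unit for LOQ
dilution_step <- function(fit) {
  xs <- sort(unique(fit$data$x[fit$data$used]))
  if (length(xs) < 2) return(1)
  stats::median(diff(xs))
}

loq_grid <- function(fit, n = 1000) {
  xs <- fit$data$x[fit$data$used]
  step <- dilution_step(fit)
  seq(min(xs) - step, max(xs) + step, length.out = n)
}

#' Confidence or prediction band of a standard curve
#'
#' Pointwise delta-method band on the log10-MFI scale, using the t
#' distribution on the fit's residual degrees of freedom. The standard
#' error of the fitted value is `se_fit(x)^2 = g(x)' Sigma g(x)` with `g`
#' the free-parameter gradient; the prediction band adds the residual
#' variance `sigma^2` and therefore contains the confidence band whenever
#' `sigma > 0`.
#'
#' @param fit A converged `curve_fit`.
#' @param x log10 concentrations at which to evaluate the band.
#' @param level Coverage level in (0, 1); default 0.95.
#' @param band `"confidence"` or `"prediction"`.
#' @return Tibble with columns `x`, `fit`, `se_fit`, `lower`, `upper`.
#' @export
curve_band <- function(fit, x, level = 0.95,
                       band = c("confidence", "prediction")) {
  band <- match.arg(band)
  stopifnot(inherits(fit, "curve_fit"), fit$converged,
            level > 0, level < 1)
  yhat <- eval_curve(fit$model, x)
  sef <- se_fit_at(fit, x)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  half <- if (band == "confidence") tq * sef else tq * sqrt(fit$sigma^2 + sef^2)
  tibble::tibble(x = x, fit = yhat, se_fit = sef,
                 lower = yhat - half, upper = yhat + half)
}

#' Limits of quantification: derivative method
#'
#' The lower and higher limits of quantification are the locations of the
#' extrema of the second derivative of the fitted curve — its "bend
#' points" — found as the roots of the third derivative by sign-change
#' bracketing on a dense grid followed by root polishing. For the EXP model
#' the third derivative is identically zero and the method is not
#' applicable.
#'
#' @param fit A converged `curve_fit` (LL4 or LL5).
#' @param grid_n Number of grid points used for root bracketing.
#' @return A `loq_estimate` with `lloq`, `hloq` and `dynamic_range` in
#'   log10 concentration units.
#' @export
loq_derivative <- function(fit, grid_n = 1000) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  if (fit$model$model_id == "EXP") {
    return(new_loq_estimate("derivative", status = "not-applicable"))
  }
  xg <- loq_grid(fit, grid_n)
  d3 <- function(x) curve_derivative(fit$model, x, order = 3)
  roots <- bracketed_roots(d3, xg)
  if (length(roots) < 2) {
    # bend points can fall outside the sampled range; widen once
    step <- dilution_step(fit)
    xg2 <- seq(min(xg) - 5 * step, max(xg) + 5 * step, length.out = grid_n * 2)
    roots <- bracketed_roots(d3, xg2)
  }
  if (length(roots) < 2) {
    return(new_loq_estimate("derivative", status = "not-estimable"))
  }
  new_loq_estimate("derivative", lloq = min(roots), hloq = max(roots),
                   settings = list(grid_n = grid_n))
}

bracketed_roots <- function(fun, grid) {
  v <- fun(grid)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  vapply(idx, function(i) {
    stats::uniroot(fun, lower = grid[i], upper = grid[i + 1],
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Limits of quantification: interval method
#'
#' The LLOQ is the concentration where the *lower* boundary of the
#' prediction interval of the standard curve crosses the *upper* boundary
#' of the confidence interval of the lower-asymptote coefficient `c`; the
#' HLOQ is where the *upper* prediction boundary crosses the *lower*
#' confidence boundary of the upper asymptote `d`. Coefficient intervals
#' are `estimate +/- t(df) * SE`; a coefficient fixed by the `constraint`
#' background has a degenerate (point) interval. Roots are searched over
#' the fitted range extended by one dilution step on each side; if several
#' crossings exist, the one closest to the midpoint `e` is taken. With no
#' sign change, or for the EXP model, the limit is not estimable /
#' applicable.
#'
#' @inheritParams curve_band
#' @param grid_n Number of grid points for root bracketing.
#' @return A `loq_estimate`.
#' @export
loq_interval <- function(fit, level = 0.95, grid_n = 1000) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  if (fit$model$model_id == "EXP") {
    return(new_loq_estimate("interval", status = "not-applicable"))
  }
  p <- fit$model$params
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  coef_ci <- function(name, side) {
    if (name %in% fit$free) {
      se <- sqrt(fit$vcov[name, name])
      p[[name]] + side * tq * se
    } else {
      p[[name]] # constrained: interval collapses to the point
    }
  }
  c_upper <- coef_ci("c", +1)
  d_lower <- coef_ci("d", -1)
  xg <- loq_grid(fit, grid_n)
  pb <- curve_band(fit, xg, level = level, band = "prediction")
  pick_root <- function(fun, grid) {
    r <- bracketed_roots(fun, grid)
    if (!length(r)) return(NA_real_)
    r[which.min(abs(r - p[["e"]]))]
  }
  f_l <- function(x) {
    b <- curve_band(fit, x, level = level, band = "prediction")
    b$lower - c_upper
  }
  f_u <- function(x) {
    b <- curve_band(fit, x, level = level, band = "prediction")
    b$upper - d_lower
  }
  lloq <- pick_root(f_l, xg)
  hloq <- pick_root(f_u, xg)
  if (!is.finite(lloq) || !is.finite(hloq) || lloq >= hloq) {
    return(new_loq_estimate("interval", status = "not-estimable",
                            settings = list(level = level)))
  }
  new_loq_estimate("interval", lloq = lloq, hloq = hloq,
                   settings = list(level = level, grid_n = grid_n))
}

#' Standard error of an inverse-predicted concentration
#'
#' Inverts the fitted curve at a log10-MFI response and propagates the
#' parameter covariance through the inverse by the delta method (implicit
#' differentiation of `f(x; theta) = y` gives
#' `grad_theta x = -g(x) / f'(x)`). By default the standard error is
#' conditional on the observed MFI, i.e. only parameter uncertainty is
#' propagated; `include_response_error = TRUE` adds the response noise term
#' `sigma^2 / f'(x)^2`. Near an asymptote `f'(x)` vanishes and the SE is
#' reported as infinite.
#'
#' @param fit A converged `curve_fit`.
#' @param y Numeric vector of log10-MFI responses.
#' @param include_response_error Add the residual-variance term?
#' @param slope_tol Absolute slope below which the SE is declared infinite.
#' @return Tibble with columns `y`, `x_hat`, `se`, `status` (`"ok"`,
#'   `"infinite"`, `"below-range"`, `"above-range"`).
#' @export
concentration_se <- function(fit, y, include_response_error = FALSE,
                             slope_tol = 1e-8) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  xh <- inverse_curve(fit$model, y, strict = FALSE)
  side <- attr(xh, "side")
  out <- tibble::tibble(y = y, x_hat = as.numeric(xh),
                        se = NA_real_, status = "ok")
  out$status[side == "below"] <- "below-range"
  out$status[side == "above"] <- "above-range"
  ok <- which(side == "ok")
  if (length(ok)) {
    se <- conc_se_at_x(fit, out$x_hat[ok], include_response_error, slope_tol)
    out$se[ok] <- se
    out$status[ok][!is.finite(se)] <- "infinite"
  }
  out
}

# delta-method SE of x at known curve locations x (y = fitted(x))
conc_se_at_x <- function(fit, x, include_response_error = FALSE,
                         slope_tol = 1e-8) {
  dydx <- curve_derivative(fit$model, x, order = 1)
  g <- free_gradient(fit, x)
  var_par <- rowSums((g %*% fit$vcov) * g) / dydx^2
  v <- var_par
  if (include_response_error) v <- v + fit$sigma^2 / dydx^2
  se <- sqrt(pmax(v, 0))
  se[abs(dydx) < slope_tol] <- Inf
  se
}

#' Coefficient of variation of an inverse-predicted concentration
#'
#' Converts a log10-scale standard error into a natural-scale coefficient
#' of variation via `CV = sqrt(exp((SE * ln 10)^2) - 1)` (the lognormal CV
#' identity).
#'
#' @param se Standard error of the log10 concentration.
#' @return CV on the natural concentration scale (0.30 means 30%).
#' @export
cv_from_se <- function(se) {
  sqrt(exp((se * log(10))^2) - 1)
}

#' Limits of quantification: coefficient-of-variation method
#'
#' Over a dense grid spanning the standard range (extended by one dilution
#' step each side), the delta-method standard error of the inverse-predicted
#' concentration is computed at the fitted response of each grid point and
#' converted to a CV via [cv_from_se()]. The LLOQ and HLOQ are the smallest
#' and largest grid concentrations whose CV does not exceed the cutoff
#' (default 20%). When even the minimum CV exceeds the cutoff the limits
#' are not estimable.
#'
#' @param fit A converged `curve_fit`.
#' @param cv_cutoff Maximum acceptable CV (0.20 = 20%).
#' @param grid_n Number of grid points.
#' @param include_response_error Passed to the SE computation; default
#'   `FALSE` (conditional on the observed MFI).
#' @return A `loq_estimate`; its `settings` carry the cutoff, grid and the
#'   minimum CV attained.
#' @export
loq_cv <- function(fit, cv_cutoff = 0.20, grid_n = 1000,
                   include_response_error = FALSE) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  if (grid_n < 2) {
    rlang::abort("grid must contain at least two points",
                 class = "beadcal_input_error")
  }
  xg <- loq_grid(fit, grid_n)
  se <- conc_se_at_x(fit, xg, include_response_error)
  cv <- cv_from_se(se)
  ok <- which(is.finite(cv) & cv <= cv_cutoff)
  settings <- list(cv_cutoff = cv_cutoff, grid_n = grid_n,
                   min_cv = suppressWarnings(min(cv[is.finite(cv)])))
  if (!length(ok)) {
    return(new_loq_estimate("cv", status = "not-estimable",
                            settings = settings))
  }
  new_loq_estimate("cv", lloq = xg[min(ok)], hloq = xg[max(ok)],
                   settings = settings)
}

#' Tidy a LOQ estimate
#'
#' @param x A `loq_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `lloq`, `hloq`, `dynamic_range`
#'   (log10 units), their natural-scale counterparts and `status`.
#' @method tidy loq_estimate
#' @export
tidy.loq_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, lloq = x$lloq, hloq = x$hloq,
    dynamic_range = x$dynamic_range,
    lloq_conc = 10^x$lloq, hloq_conc = 10^x$hloq,
    status = x$status
  )
}
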