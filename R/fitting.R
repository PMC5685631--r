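#' Fit a standard curve with sequential model fallback
#'
#' Fits log10(MFI) against log10(expected concentration) by nonlinear least
#' squares, trying each model family in `model_order` until one converges
#' (by default LL5, then LL4, then EXP). The chosen blank-control background
#' treatment is applied first (see [apply_background()]); flagged wells and
#' wells excluded by the background step never enter the objective. Every
#' attempt is recorded in the fit's `fallback_log`, so non-convergence and
#' model changes are visible, and total failure returns a non-converged
#' `curve_fit` carrying the log rather than an exception.
#'
#' Log-logistic fitting uses Levenberg–Marquardt least squares
#' ([minpack.lm::nlsLM()]) with self-start values: asymptote guesses just
#' outside the observed response range, `e` at the x whose response is
#' closest to midrange, `b` from a logit-linearized regression and `f = 1`.
#' Under the `constraint` background the lower-asymptote coefficient is held
#' at log10 of the blank geometric mean and drops out of the free-parameter
#' set (and of the covariance).
#'
#' @param std Standard table (see [as_standard_table()]).
#' @param blanks Optional blank table; required by `subtract`, `include`
#'   and `constraint` backgrounds.
#' @param bkg_method Background treatment, one of `"ignore"`, `"subtract"`,
#'   `"include"`, `"constraint"`.
#' @param model_order Character vector of model ids to attempt in order,
#'   from `"LL5"`, `"LL4"`, `"EXP"`. Supply a single id to pin the model.
#' @param dilution_factor Dilution factor for the `include` background;
#'   inferred when `NULL`.
#' @param control List of fitting controls: `maxiter` (default 200), `ftol`
#'   and `ptol` (default `1e-8`, relative RSS / parameter-step convergence
#'   tolerances).
#' @return An object of class `curve_fit`. Key fields: `model`
#'   ([curve_model] including any fixed coefficient), `coef` and `vcov`
#'   (free parameters only), `sigma` (residual SD on log10 MFI), `df`
#'   (residual degrees of freedom), `n_used`, `data` (per-well tibble with
#'   `x`, `y`, `used`, `.fitted`, `.resid`, `.std_resid`), `excluded`,
#'   `bkg_method`, `bkg_value`, `fallback_log` and `converged`.
#' @export
fit_standard_curve <- function(std, blanks = NULL, bkg_method = "ignore",
                               model_order = c("LL5", "LL4", "EXP"),
                               dilution_factor = NULL,
                               control = list()) {
  stopifnot(all(model_order %in% c("LL5", "LL4", "EXP")))
  ctrl <- utils::modifyList(list(maxiter = 200, ftol = 1e-8, ptol = 1e-8),
                            control)
  bkg <- apply_background(std, blanks, bkg_method,
                          dilution_factor = dilution_factor)
  tab <- bkg$standards
  tab$x <- log10(tab$expected_conc)
  tab$y <- NA_real_
  pos <- which(tab$mfi_adj > 0)
  tab$y[pos] <- log10(tab$mfi_adj[pos])
  tab$used <- !tab$flagged & is.na(tab$exclude_reason) &
    is.finite(tab$x) & is.finite(tab$y)

  d <- tab[tab$used, c("x", "y")]
  log <- list()
  fit <- NULL
  for (m in model_order) {
    att <- try_fit_model(m, d, constraint = bkg$constraint_log10, ctrl = ctrl)
    log[[length(log) + 1]] <- tibble::tibble(
      model_id = m, converged = att$converged, message = att$message
    )
    if (att$converged) {
      fit <- att
      break
    }
  }
  fallback_log <- dplyr::bind_rows(log)

  excluded <- dplyr::bind_rows(
    tab[!is.na(tab$exclude_reason),
        c("plate_id", "well", "analyte", "exclude_reason")] |>
      dplyr::rename(reason = "exclude_reason"),
    tab[tab$flagged, c("plate_id", "well", "analyte")] |>
      dplyr::mutate(reason = "flagged")
  )

  base <- list(
    data = tab, excluded = excluded, bkg_method = bkg$method,
    bkg_value = bkg$blank_gm, constraint_log10 = bkg$constraint_log10,
    fallback_log = fallback_log,
    plate_id = if (nrow(tab)) tab$plate_id[[1]] else NA_character_,
    analyte = if (nrow(tab)) tab$analyte[[1]] else NA_character_
  )
  if (is.null(fit)) {
    return(structure(c(base, list(converged = FALSE, model = NULL,
                                  coef = NULL, vcov = NULL, free = character(),
                                  sigma = NA_real_, df = NA_integer_,
                                  n_used = nrow(d))),
                     class = "curve_fit"))
  }

  tab$.fitted <- ifelse(is.finite(tab$x), eval_curve(fit$model, tab$x), NA_real_)
  tab$.resid <- ifelse(tab$used, tab$y - tab$.fitted, NA_real_)
  # an (effectively) exact fit has no meaningful residual scale; report
  # standardized residuals as zero instead of noise/noise ratios
  tab$.std_resid <- if (fit$sigma < 1e-8) {
    ifelse(tab$used, 0, NA_real_)
  } else {
    tab$.resid / fit$sigma
  }
  base$data <- tab
  structure(c(base,
              list(converged = TRUE, model = fit$model,
                   coef = fit$coef, vcov = fit$vcov, free = fit$free,
                   sigma = fit$sigma, df = fit$df, n_used = nrow(d))),
            class = "curve_fit")
}

# Self-start values for the log-logistic families (see Details of
# fit_standard_curve); returns NULL when the logit linearization degenerates.
ll_start <- function(d) {
  rng <- diff(range(d$y))
  c0 <- min(d$y) - 0.05 * max(rng, 0.1)
  d0 <- max(d$y) + 0.05 * max(rng, 0.1)
  e0 <- d$x[which.min(abs(d$y - (c0 + d0) / 2))]
  w <- log10((d0 - d$y) / (d$y - c0))
  ok <- is.finite(w) & is.finite(d$x)
  if (sum(ok) < 2 || stats::sd(d$x[ok]) == 0) return(NULL)
  co <- stats::coef(stats::lm(w[ok] ~ d$x[ok]))
  b0 <- unname(co[2])
  if (!is.finite(b0) || b0 == 0) b0 <- -1
  e_lin <- -unname(co[1]) / b0
  if (is.finite(e_lin) && e_lin >= min(d$x) && e_lin <= max(d$x)) e0 <- e_lin
  list(b = b0, c = c0, d = d0, e = e0)
}

try_fit_model <- function(model_id, d, constraint = NA_real_, ctrl) {
  free <- model_param_names[[model_id]]
  fixed <- NULL
  if (is.finite(constraint)) {
    fixed_name <- if (model_id == "EXP") "a0" else "c"
    free <- setdiff(free, fixed_name)
    fixed <- stats::setNames(constraint, fixed_name)
  }
  if (nrow(d) < length(free) + 1) {
    return(list(converged = FALSE,
                message = sprintf("%d points < %d required", nrow(d),
                                  length(free) + 1)))
  }

  res <- tryCatch({
    if (model_id == "EXP") {
      if (is.null(fixed)) {
        lmfit <- stats::lm(y ~ x, data = d)
        coefs <- stats::setNames(stats::coef(lmfit), c("a0", "b"))
        vc <- stats::vcov(lmfit)
        dimnames(vc) <- list(c("a0", "b"), c("a0", "b"))
        sm <- summary(lmfit)
        list(coef = coefs, vcov = vc, sigma = sm$sigma,
             df = lmfit$df.residual)
      } else {
        yy <- d$y - fixed[["a0"]]
        b <- sum(yy * d$x) / sum(d$x^2)
        resid <- yy - b * d$x
        df <- nrow(d) - 1
        s2 <- sum(resid^2) / df
        list(coef = c(b = b), vcov = matrix(s2 / sum(d$x^2), 1, 1,
                                            dimnames = list("b", "b")),
             sigma = sqrt(s2), df = df)
      }
    } else {
      start <- ll_start(d)
      if (is.null(start)) stop("degenerate start values")
      if (model_id == "LL5") start$f <- 1
      dat <- d
      if (!is.null(fixed)) {
        start$c <- NULL
        dat$C0 <- fixed[["c"]]
        form <- if (model_id == "LL5") {
          y ~ C0 + (d - C0) / (1 + 10^(b * (x - e)))^f
        } else {
          y ~ C0 + (d - C0) / (1 + 10^(b * (x - e)))
        }
      } else {
        form <- if (model_id == "LL5") {
          y ~ c + (d - c) / (1 + 10^(b * (x - e)))^f
        } else {
          y ~ c + (d - c) / (1 + 10^(b * (x - e)))
        }
      }
      nls_fit <- minpack.lm::nlsLM(
        form, data = dat, start = start,
        control = minpack.lm::nls.lm.control(
          maxiter = ctrl$maxiter, ftol = ctrl$ftol, ptol = ctrl$ptol)
      )
      sm <- summary(nls_fit)
      vc <- stats::vcov(nls_fit)
      cf <- stats::coef(nls_fit)
      if (any(!is.finite(vc)) || any(!is.finite(cf))) stop("non-finite estimates")
      # enforce the model's parameter domain; a fit outside it is a failure
      full <- c(cf, fixed)
      validate_curve_params(model_id, full)
      list(coef = cf, vcov = vc, sigma = sm$sigma,
           df = stats::df.residual(nls_fit))
    }
  }, error = function(e) e)

  if (inherits(res, "error")) {
    return(list(converged = FALSE, message = conditionMessage(res)))
  }
  full <- c(res$coef, fixed)[model_param_names[[model_id]]]
  model <- new_curve_model(model_id, full)
  list(converged = TRUE, message = "converged", model = model,
       coef = res$coef, vcov = res$vcov[free, free, drop = FALSE],
       free = free, sigma = res$sigma, df = res$df)
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<curve_fit> no model converged\n")
    print(x$fallback_log)
    return(invisible(x))
  }
  cat("<curve_fit ", x$model$model_id, "> ", x$analyte, " / plate ",
      x$plate_id, "\n", sep = "")
  cat("  background:", x$bkg_method,
      if (is.finite(x$bkg_value)) sprintf("(blank GM %.1f)", x$bkg_value),
      "\n")
  cat("  n_used:", x$n_used, " sigma:", signif(x$sigma, 4),
      " df:", x$df, "\n")
  print(round(x$model$params, 4))
  invisible(x)
}

#' Goodness-of-fit statistics for a standard curve
#'
#' R-squared (plain and adjusted) on log10 MFI, the Akaike information
#' criterion under the Gaussian likelihood with the residual variance
#' counted as a parameter (`AIC = n log(2*pi) + n log(RSS/n) + n + 2(p+1)`),
#' and the Neill lack-of-fit p-value (see [neill_test()]).
#'
#' @param fit A converged `curve_fit`.
#' @return One-row tibble: `model_id`, `n`, `p`, `rss`, `r2`, `adjusted_r2`,
#'   `aic`, `neill_p`, `neill_status`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "curve_fit"))
  if (!fit$converged) {
    rlang::abort("fit did not converge; no statistics available",
                 class = "beadcal_fit_error")
  }
  r <- fit$data$.resid[fit$data$used]
  y <- fit$data$y[fit$data$used]
  n <- length(r)
  p <- length(fit$free)
  rss <- sum(r^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  adj <- if (tss == 0) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p)
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * (p + 1)
  nt <- neill_test(fit)
  tibble::tibble(
    model_id = fit$model$model_id, n = n, p = p, rss = rss,
    r2 = r2, adjusted_r2 = adj, aic = aic,
    neill_p = nt$p_value, neill_status = nt$status
  )
}

#' Neill lack-of-fit test
#'
#' ANOVA-based lack-of-fit test for a nonlinear regression with replicated
#' design points. Residual variation is split into pure error (within groups
#' of replicates) and lack of fit;
#' `F = (SS_lof / (m - p)) / (SS_pe / (n - m))` is referred to an F
#' distribution with `(m - p, n - m)` degrees of freedom. By default wells
#' sharing an identical expected concentration form a group (replicated
#' dilutions give pure error). When the grouping is degenerate (no
#' replicates anywhere, or `m` outside `(p, n)`) the test is reported as
#' undefined rather than guessing a grouping.
#'
#' @param fit A converged `curve_fit`.
#' @param groups Optional grouping vector, one entry per used point (in the
#'   row order of `fit$data[fit$data$used, ]`).
#' @return One-row tibble: `status` (`"ok"` or `"undefined"`), `statistic`,
#'   `df1`, `df2`, `p_value`, `message`.
#' @export
neill_test <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "curve_fit"))
  if (!fit$converged) {
    rlang::abort("fit did not converge", class = "beadcal_fit_error")
  }
  used <- fit$data[fit$data$used, ]
  n <- nrow(used)
  p <- length(fit$free)
  if (is.null(groups)) groups <- factor(used$x)
  groups <- factor(groups)
  m <- nlevels(groups)
  undef <- function(msg) tibble::tibble(
    status = "undefined", statistic = NA_real_, df1 = NA_real_,
    df2 = NA_real_, p_value = NA_real_, message = msg
  )
  if (length(groups) != n) {
    rlang::abort("groups must have one entry per used point",
                 class = "beadcal_input_error")
  }
  if (m <= p || m >= n) {
    return(undef(sprintf("need p < m < n (p=%d, m=%d, n=%d)", p, m, n)))
  }
  if (!any(table(groups) >= 2)) {
    return(undef("no replicated design points: pure error is not estimable"))
  }
  rss <- sum(used$.resid^2)
  gm <- tapply(used$y, groups, mean)
  ss_pe <- sum((used$y - gm[as.character(groups)])^2)
  ss_lof <- max(rss - ss_pe, 0)
  f <- (ss_lof / (m - p)) / (ss_pe / (n - m))
  tibble::tibble(
    status = "ok", statistic = f, df1 = m - p, df2 = n - m,
    p_value = stats::pf(f, m - p, n - m, lower.tail = FALSE),
    message = "ok"
  )
}

#' Coefficient summary across fits
#'
#' One row per estimated coefficient per fit: estimate, standard error
#' (square root of the covariance diagonal), t statistic against zero and
#' the two-sided p-value on the fit's residual degrees of freedom. Fixed
#' (constrained) coefficients are not tested and do not appear; fits that
#' failed to converge contribute a single status row.
#'
#' @param fits A `curve_fit` or a list of them.
#' @return Tibble with columns `plate_id`, `analyte`, `model_id`, `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `status`.
#' @export
summary_coefficients <- function(fits) {
  if (inherits(fits, "curve_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    if (!f$converged) {
      return(tibble::tibble(
        plate_id = f$plate_id, analyte = f$analyte, model_id = NA_character_,
        term = NA_character_, estimate = NA_real_, std_error = NA_real_,
        statistic = NA_real_, p_value = NA_real_, status = "fit-failure"
      ))
    }
    se <- sqrt(diag(f$vcov))
    est <- f$coef[f$free]
    tstat <- est / se
    tibble::tibble(
      plate_id = f$plate_id, analyte = f$analyte,
      model_id = f$model$model_id, term = f$free,
      estimate = unname(est), std_error = unname(se),
      statistic = unname(tstat),
      p_value = 2 * stats::pt(abs(unname(tstat)), df = f$df,
                              lower.tail = FALSE),
      status = "ok"
    )
  })
}
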