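#' Inverse-predict the concentration of one test response
#'
#' Maps a natural-scale MFI through a plate's fitted standard curve to a
#' concentration, with a delta-method standard error and a status against
#' the supplied limits of quantification. The test well receives exactly
#' the background treatment of the curve it is calibrated against: under
#' `subtract` the blank geometric mean is subtracted before the log10
#' transform (an MFI at or below the blank GM cannot be placed on the
#' curve), while `ignore`, `include` and `constraint` leave the test MFI
#' untouched.
#'
#' @param fit A converged `curve_fit`.
#' @param loq A `loq_estimate` for the same fit (any method), or `NULL` to
#'   skip LOQ status assignment.
#' @param mfi Positive natural-scale MFI values.
#' @param include_response_error Passed to [concentration_se()].
#' @return Tibble with one row per input MFI: `mfi`, `y` (log10 adjusted
#'   response), `x_hat` (log10 concentration), `conc` (`10^x_hat`), `se_x`,
#'   `cv` (natural-scale, via [cv_from_se()]) and `status`, one of
#'   `"quantified"`, `"below-lloq"`, `"above-hloq"`, `"below-curve-range"`,
#'   `"above-curve-range"`, `"not-invertible"`.
#' @export
estimate_concentration <- function(fit, loq = NULL, mfi,
                                   include_response_error = FALSE) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  if (any(mfi <= 0 | !is.finite(mfi))) {
    rlang::abort("test MFI must be positive and finite",
                 class = "beadcal_input_error")
  }
  adj <- if (fit$bkg_method == "subtract") mfi - fit$bkg_value else mfi
  y <- ifelse(adj > 0, log10(adj), NA_real_)
  out <- tibble::tibble(mfi = mfi, y = y, x_hat = NA_real_,
                        conc = NA_real_, se_x = NA_real_, cv = NA_real_,
                        status = "not-invertible")
  ok <- which(is.finite(y))
  if (length(ok)) {
    cs <- concentration_se(fit, y[ok],
                           include_response_error = include_response_error)
    out$x_hat[ok] <- cs$x_hat
    out$se_x[ok] <- cs$se
    out$conc[ok] <- 10^cs$x_hat
    out$cv[ok] <- cv_from_se(cs$se)
    st <- rep("quantified", length(ok))
    st[cs$status == "below-range"] <- "below-curve-range"
    st[cs$status == "above-range"] <- "above-curve-range"
    if (!is.null(loq) && loq$status == "ok") {
      inv <- cs$status %in% c("ok", "infinite")
      st[inv & cs$x_hat < loq$lloq] <- "below-lloq"
      st[inv & cs$x_hat > loq$hloq] <- "above-hloq"
    }
    out$status[ok] <- st
  }
  out
}

#' Calibrate a table of test wells against fitted curves
#'
#' Applies [estimate_concentration()] row-wise, matching each test well to
#' the fit (and LOQ estimate) of its (plate, analyte). Every input row
#' appears in the output exactly once; wells without a matching fit are
#' returned with status `"missing-fit"` rather than dropped.
#'
#' @param fits A list of converged `curve_fit` objects (any names); matched
#'   to rows by their `plate_id` and `analyte` fields.
#' @param loqs Optional list of `loq_estimate`s parallel to `fits` (same
#'   order), or `NULL`.
#' @param tests Test table: standard-well layout without `expected_conc`
#'   (see [as_standard_table()]).
#' @return Tibble with the test identifiers plus the
#'   [estimate_concentration()] columns.
#' @export
batch_calibrate <- function(fits, loqs = NULL, tests) {
  if (inherits(fits, "curve_fit")) fits <- list(fits)
  if (inherits(loqs, "loq_estimate")) loqs <- list(loqs)
  tests <- as_standard_table(tests, require_conc = FALSE)
  if (!nrow(tests)) {
    return(dplyr::mutate(tests, y = numeric(0), x_hat = numeric(0),
                         conc = numeric(0), se_x = numeric(0),
                         cv = numeric(0), status = character(0)))
  }
  key <- function(p, a) paste(p, a, sep = "\r")
  fit_keys <- vapply(fits, function(f) key(f$plate_id, f$analyte), "")
  groups <- split(seq_len(nrow(tests)), key(tests$plate_id, tests$analyte))
  res <- purrr::map_dfr(names(groups), function(k) {
    rows <- tests[groups[[k]], ]
    i <- match(k, fit_keys)
    if (is.na(i) || !fits[[i]]$converged) {
      return(dplyr::mutate(rows, y = NA_real_, x_hat = NA_real_,
                           conc = NA_real_, se_x = NA_real_, cv = NA_real_,
                           status = "missing-fit"))
    }
    loq <- if (!is.null(loqs)) loqs[[i]] else NULL
    est <- estimate_concentration(fits[[i]], loq, rows$mfi)
    dplyr::bind_cols(rows, est[setdiff(names(est), "mfi")])
  })
  res[order(match(paste(res$plate_id, res$well, res$analyte),
                  paste(tests$plate_id, tests$well, tests$analyte))), ]
}
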