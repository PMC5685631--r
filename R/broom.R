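#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted standard curve
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @return Coefficient tibble (see [summary_coefficients()]) with one row
#'   per free parameter.
#' @method tidy curve_fit
#' @export
tidy.curve_fit <- function(x, ...) {
  summary_coefficients(x)[, c("term", "estimate", "std_error",
                              "statistic", "p_value")]
}

#' One-row summary of a fitted standard curve
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @return One-row tibble: identifiers, model id, background method,
#'   convergence flag, `n_used`, `sigma`, `df` and the [fit_statistics()]
#'   columns.
#' @method glance curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  base <- tibble::tibble(
    plate_id = x$plate_id, analyte = x$analyte,
    bkg_method = x$bkg_method, converged = x$converged,
    n_used = x$n_used, sigma = x$sigma, df = x$df
  )
  if (!x$converged) return(base)
  dplyr::bind_cols(base, fit_statistics(x))
}

#' Per-well fit details
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @return The fit's per-well tibble (`x`, `y`, `used`, `.fitted`,
#'   `.resid`, `.std_resid`, exclusion reasons).
#' @method augment curve_fit
#' @export
augment.curve_fit <- function(x, ...) {
  tibble::as_tibble(x$data)
}
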