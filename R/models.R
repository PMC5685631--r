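#' Dose-response curve models
#'
#' Construct a dose-response curve model in the log10/log10 parameterization
#' used throughout beadcal: `x` is log10 expected concentration and `y` is
#' log10 MFI. Three families are supported.
#'
#' * `ll5_model()`: five-parameter log-logistic,
#'   `y = c + (d - c) / (1 + 10^(b (x - e)))^f`.
#' * `ll4_model()`: four-parameter log-logistic, the LL5 with asymmetry
#'   `f = 1`.
#' * `exp_model()`: exponential growth, linear on the log10/log10 scale:
#'   `y = a0 + b x` where `a0 = log10(y0)` and `y0` is the response in the
#'   absence of analyte on the natural MFI scale.
#'
#' Sign convention: under this parameterization `10^(b (x - e)) -> 0` as
#' `x -> Inf`, so an *increasing* standard curve has a *negative* slope
#' parameter `b`. The slope is never silently flipped.
#'
#' @param b Slope around `e` (LL5/LL4) or growth rate per log10-concentration
#'   unit (EXP). An increasing log-logistic curve has `b < 0`.
#' @param c Lower asymptote, log10-MFI units.
#' @param d Upper asymptote, log10-MFI units; must exceed `c`.
#' @param e log10 concentration producing the halfway response (exactly
#'   halfway when `f = 1`).
#' @param f Asymmetry parameter, `> 0`. `f = 1` recovers the LL4.
#' @param a0 Intercept of the EXP model, `log10(y0)`.
#'
#' @return An object of class `curve_model`: a list with `model_id`
#'   (`"LL5"`, `"LL4"` or `"EXP"`) and the named coefficient vector `params`.
#' @examples
#' m <- ll4_model(b = -1, c = 1, d = 3, e = 1)
#' eval_curve(m, x = 1) # halfway response: 2
#' @name curve_model
NULL

model_param_names <- list(
  LL5 = c("b", "c", "d", "e", "f"),
  LL4 = c("b", "c", "d", "e"),
  EXP = c("a0", "b")
)

model_expr <- list(
  LL5 = quote(c + (d - c) / (1 + 10^(b * (x - e)))^f),
  LL4 = quote(c + (d - c) / (1 + 10^(b * (x - e)))),
  EXP = quote(a0 + b * x)
)

new_curve_model <- function(model_id, params) {
  structure(list(model_id = model_id, params = params), class = "curve_model")
}

validate_curve_params <- function(model_id, params) {
  nm <- model_param_names[[model_id]]
  if (!all(nm %in% names(params))) {
    rlang::abort(
      paste0(model_id, " model needs parameters ", paste(nm, collapse = ", ")),
      class = "beadcal_param_error"
    )
  }
  params <- params[nm]
  if (any(!is.finite(params))) {
    rlang::abort("curve parameters must be finite", class = "beadcal_param_error")
  }
  if (model_id %in% c("LL5", "LL4") && params[["c"]] >= params[["d"]]) {
    rlang::abort(
      "lower asymptote c must lie below upper asymptote d",
      class = "beadcal_param_error"
    )
  }
  if (model_id == "LL5" && params[["f"]] <= 0) {
    rlang::abort("asymmetry parameter f must be positive", class = "beadcal_param_error")
  }
  params
}

#' @rdname curve_model
#' @export
ll5_model <- function(b, c, d, e, f) {
  p <- validate_curve_params("LL5", c(b = unname(b), c = unname(c),
                                      d = unname(d), e = unname(e),
                                      f = unname(f)))
  new_curve_model("LL5", p)
}

#' @rdname curve_model
#' @export
ll4_model <- function(b, c, d, e) {
  p <- validate_curve_params("LL4", c(b = unname(b), c = unname(c),
                                      d = unname(d), e = unname(e)))
  new_curve_model("LL4", p)
}

#' @rdname curve_model
#' @export
exp_model <- function(a0, b) {
  p <- validate_curve_params("EXP", c(a0 = unname(a0), b = unname(b)))
  new_curve_model("EXP", p)
}

#' @export
print.curve_model <- function(x, ...) {
  cat("<curve_model ", x$model_id, ">\n", sep = "")
  print(round(x$params, 6))
  invisible(x)
}

param_env <- function(model, x = NULL) {
  env <- list2env(as.list(model$params), parent = baseenv())
  if (!is.null(x)) assign("x", x, envir = env)
  env
}

#' Evaluate a standard-curve model
#'
#' Computes the model response (log10 MFI) at log10 concentrations `x`.
#'
#' @param model A [curve_model].
#' @param x Numeric vector of log10 concentrations.
#' @return Numeric vector of log10-MFI responses, same length as `x`.
#' @export
eval_curve <- function(model, x) {
  stopifnot(inherits(model, "curve_model"))
  validate_curve_params(model$model_id, model$params)
  eval(model_expr[[model$model_id]], envir = param_env(model, x))
}

#' Invert a standard-curve model
#'
#' Maps a log10-MFI response back to log10 concentration. For the
#' log-logistic models the response must lie strictly between the asymptotes
#' `c` and `d`; for the EXP model the slope must be nonzero.
#'
#' @param model A [curve_model].
#' @param y Numeric vector of log10-MFI responses.
#' @param strict If `TRUE` (default) responses outside the invertible range
#'   raise a classed error (`beadcal_below_asymptote` /
#'   `beadcal_above_asymptote`). If `FALSE`, out-of-range entries are
#'   returned as `NA` and the range side is reported in the `"side"`
#'   attribute (`"ok"`, `"below"`, `"above"`).
#' @return Numeric vector of log10 concentrations.
#' @export
inverse_curve <- function(model, y, strict = TRUE) {
  stopifnot(inherits(model, "curve_model"))
  p <- validate_curve_params(model$model_id, model$params)
  if (model$model_id == "EXP") {
    if (p[["b"]] == 0) {
      rlang::abort("EXP model with zero slope is not invertible",
                   class = "beadcal_param_error")
    }
    return(structure((y - p[["a0"]]) / p[["b"]], side = rep("ok", length(y))))
  }
  f <- if (model$model_id == "LL5") p[["f"]] else 1
  below <- y <= p[["c"]]
  above <- y >= p[["d"]]
  side <- ifelse(below, "below", ifelse(above, "above", "ok"))
  if (strict && any(below)) {
    rlang::abort("response at or below the lower asymptote c",
                 class = c("beadcal_below_asymptote", "beadcal_range_error"))
  }
  if (strict && any(above)) {
    rlang::abort("response at or above the upper asymptote d",
                 class = c("beadcal_above_asymptote", "beadcal_range_error"))
  }
  x <- rep(NA_real_, length(y))
  ok <- !below & !above
  x[ok] <- p[["e"]] + (1 / p[["b"]]) *
    log10(((p[["d"]] - p[["c"]]) / (y[ok] - p[["c"]]))^(1 / f) - 1)
  structure(x, side = side)
}

deriv_expr <- function(model_id, order) {
  ex <- model_expr[[model_id]]
  for (i in seq_len(order)) ex <- stats::D(ex, "x")
  ex
}

#' Analytic derivatives of a standard curve
#'
#' First to third derivative of the model response with respect to log10
#' concentration, obtained by symbolic differentiation of the model
#' expression (not finite differences). The derivative-method limits of
#' quantification are the roots of the third derivative.
#'
#' @inheritParams eval_curve
#' @param order Derivative order, 1, 2 or 3.
#' @return Numeric vector of derivative values at `x`.
#' @export
curve_derivative <- function(model, x, order = 1) {
  stopifnot(inherits(model, "curve_model"))
  if (!order %in% 1:3) {
    rlang::abort("order must be 1, 2 or 3", class = "beadcal_param_error")
  }
  validate_curve_params(model$model_id, model$params)
  val <- eval(deriv_expr(model$model_id, order), envir = param_env(model, x))
  rep_len(val, length(x))
}

#' Gradient of the curve with respect to its parameters
#'
#' Partial derivatives of the model response at `x` with respect to each
#' coefficient, in the model's coefficient order. This is the `g(x)` vector
#' of the delta method used for confidence bands and inverse-prediction
#' standard errors.
#'
#' @inheritParams eval_curve
#' @return A numeric matrix with `length(x)` rows and one column per
#'   parameter, with the parameter names as column names.
#' @export
param_gradient <- function(model, x) {
  stopifnot(inherits(model, "curve_model"))
  validate_curve_params(model$model_id, model$params)
  nm <- model_param_names[[model$model_id]]
  env <- param_env(model, x)
  g <- vapply(nm, function(p) {
    rep_len(eval(stats::D(model_expr[[model$model_id]], p), envir = env),
            length(x))
  }, numeric(length(x)))
  if (length(x) == 1L) g <- matrix(g, nrow = 1, dimnames = list(NULL, nm))
  g
}
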