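#' Standard-curve plot
#'
#' Fitted curve with observed standard points on the log10/log10 scale,
#' a confidence or prediction band, and a horizontal line at the blank
#' geometric mean when background information was used. Flagged or
#' excluded points are drawn as empty circles; they are visible but take
#' no part in the fitted curve.
#'
#' @param fit A converged `curve_fit`.
#' @param band `"confidence"`, `"prediction"` or `"none"`.
#' @param level Band coverage level.
#' @return A ggplot object.
#' @export
plot_standard_curve <- function(fit, band = c("confidence", "prediction", "none"),
                                level = 0.95) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  band <- match.arg(band)
  d <- fit$data[is.finite(fit$data$x) & is.finite(fit$data$y), ]
  xg <- seq(min(d$x), max(d$x), length.out = 200)
  curve <- tibble::tibble(x = xg, y = eval_curve(fit$model, xg))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  if (band != "none") {
    cb <- curve_band(fit, xg, level = level, band = band)
    p <- p + ggplot2::geom_ribbon(
      data = cb,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  if (is.finite(fit$bkg_value)) {
    p <- p + ggplot2::geom_hline(yintercept = log10(fit$bkg_value),
                                 linetype = "dashed", colour = "darkgreen")
  }
  p +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "log10 expected concentration", y = "log10 MFI",
      title = sprintf("%s / %s (%s, bkg %s)", fit$analyte, fit$plate_id,
                      fit$model$model_id, fit$bkg_method)
    ) +
    ggplot2::theme_minimal()
}

#' Residual-vs-fitted plot
#'
#' Standardized residuals against fitted log10 MFI; points beyond the
#' cutoff are highlighted and labeled with their well position.
#'
#' @param fit A converged `curve_fit`.
#' @param cutoff Outlier cutoff on `|standardized residual|`.
#' @return A ggplot object.
#' @export
plot_residuals <- function(fit, cutoff = 2) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  d <- fit$data[fit$data$used, ]
  d$beyond <- abs(d$.std_resid) > cutoff
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.fitted, y = .data$.std_resid)) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$beyond)) +
    ggplot2::geom_text(data = d[d$beyond, ],
                       ggplot2::aes(label = .data$well),
                       vjust = -0.8, size = 3, colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "fitted log10 MFI", y = "standardized residual",
                  title = paste0(fit$analyte, ": residuals")) +
    ggplot2::theme_minimal()
}

#' Normal QQ plot of standardized residuals
#'
#' @param fit A converged `curve_fit`.
#' @return A ggplot object with a 45-degree reference line.
#' @export
plot_qq <- function(fit) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged)
  r <- sort(fit$data$.std_resid[fit$data$used])
  d <- tibble::tibble(
    theoretical = stats::qnorm(stats::ppoints(length(r))),
    sample = r
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normal quantiles", y = "standardized residuals",
                  title = paste0(fit$analyte, ": QQ plot")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot curve_fit
#' @export
autoplot.curve_fit <- function(object, type = c("curve", "residuals", "qq"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         curve = plot_standard_curve(object, ...),
         residuals = plot_residuals(object, ...),
         qq = plot_qq(object))
}

#' @export
plot.curve_fit <- function(x, ...) print(autoplot.curve_fit(x, ...))
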