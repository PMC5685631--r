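#' Flag standard-curve outliers on standardized residuals
#'
#' Returns every used standard point whose absolute standardized residual
#' (raw residual divided by the fit's residual SD) exceeds the cutoff.
#' The default cutoff of 2 follows common assay QC practice; any positive
#' cutoff may be supplied. Rows are ordered by plate, analyte, well.
#'
#' @param fit A converged `curve_fit`.
#' @param cutoff Positive cutoff on `|standardized residual|`.
#' @return Tibble with columns `plate_id`, `analyte`, `well`, `sample`,
#'   `std_resid`, `cutoff`.
#' @export
get_outliers <- function(fit, cutoff = 2) {
  stopifnot(inherits(fit, "curve_fit"), fit$converged, cutoff > 0)
  d <- fit$data
  hit <- d$used & is.finite(d$.std_resid) & abs(d$.std_resid) > cutoff
  out <- d[hit, c("plate_id", "analyte", "well", "sample", ".std_resid")]
  names(out)[names(out) == ".std_resid"] <- "std_resid"
  out$cutoff <- cutoff
  dplyr::arrange(out, .data$plate_id, .data$analyte, .data$well)
}

#' Flag wells and refit the standard curve
#'
#' Marks the named wells as flagged in the standard table and refits; the
#' flagged points are kept in the table (and drawn as empty circles by the
#' plot methods) but excluded from the least-squares objective, so the
#' original and refitted curves can be compared. Flagging an
#' already-flagged well is a no-op, making the operation idempotent.
#'
#' @param std Standard table.
#' @param wells Either a character vector of well positions (applied to all
#'   analytes in the table) or a data frame with columns among `plate_id`,
#'   `analyte`, `well` (e.g. the output of [get_outliers()]).
#' @param blanks,bkg_method,model_order,dilution_factor,control Passed to
#'   [fit_standard_curve()].
#' @return List with `standards` (the flagged table) and `fit` (the new
#'   `curve_fit`).
#' @export
flag_and_refit <- function(std, wells, blanks = NULL, bkg_method = "ignore",
                           model_order = c("LL5", "LL4", "EXP"),
                           dilution_factor = NULL, control = list()) {
  std <- as_standard_table(std)
  if (is.data.frame(wells)) {
    keys <- c("plate_id", "analyte", "well")
    use <- intersect(keys, names(wells))
    if (!"well" %in% use) {
      rlang::abort("well column required to identify points to flag",
                   class = "beadcal_input_error")
    }
    tab_key <- do.call(paste, c(std[use], sep = "\r"))
    flag_key <- unique(do.call(paste, c(wells[use], sep = "\r")))
    unknown <- setdiff(flag_key, tab_key)
    if (length(unknown)) {
      rlang::abort(paste0("unknown wells: ",
                          paste(gsub("\r", "/", unknown), collapse = ", ")),
                   class = "beadcal_input_error")
    }
    std$flagged <- std$flagged | tab_key %in% flag_key
  } else {
    unknown <- setdiff(wells, std$well)
    if (length(unknown)) {
      rlang::abort(paste0("unknown wells: ", paste(unknown, collapse = ", ")),
                   class = "beadcal_input_error")
    }
    std$flagged <- std$flagged | std$well %in% wells
  }
  fit <- fit_standard_curve(std, blanks = blanks, bkg_method = bkg_method,
                            model_order = model_order,
                            dilution_factor = dilution_factor,
                            control = control)
  list(standards = std, fit = fit)
}

#' Intraclass correlation from ANOVA mean squares
#'
#' Shrout–Fleiss intraclass correlation for a subjects-by-raters (or runs)
#' matrix of repeated measurements, used e.g. to assess reliability across
#' assay operators. One-way and two-way random-effects models, consistency
#' or absolute-agreement definitions, and single- or average-measure units
#' are supported, with F-based confidence intervals. A negative ANOVA
#' estimate is reported clipped at zero with status `"clipped-negative"`
#' (the raw value is kept in `icc_raw`).
#'
#' @param wide Data frame or matrix, subjects in rows, raters/runs in
#'   columns. Rows with any missing value are dropped.
#' @param model `"oneway"` or `"twoway"` (random raters).
#' @param type `"consistency"` or `"agreement"` (ignored for `oneway`,
#'   which is inherently an agreement index).
#' @param unit `"single"` or `"average"`.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `model`, `type`, `unit`, `n`, `k`, `icc`,
#'   `icc_raw`, `lower`, `upper`, `status`.
#' @export
intra_icc <- function(wide, model = c("oneway", "twoway"),
                      type = c("consistency", "agreement"),
                      unit = c("single", "average"), conf_level = 0.95) {
  model <- match.arg(model)
  type <- match.arg(type)
  unit <- match.arg(unit)
  m <- as.matrix(wide)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    rlang::abort("need at least 2 subjects and 2 raters/runs",
                 class = "beadcal_input_error")
  }
  alpha <- 1 - conf_level
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  msr <- ss_rows / (n - 1)                       # between-subject
  msw <- (ss_tot - ss_rows) / (n * (k - 1))      # within-subject (one-way)
  msc <- ss_cols / (k - 1)                       # between-rater
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))

  if (model == "oneway") {
    type <- "agreement"
    icc_s <- (msr - msw) / (msr + (k - 1) * msw)
    fobs <- msr / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo_s <- (fl - 1) / (fl + k - 1)
    up_s <- (fu - 1) / (fu + k - 1)
  } else if (type == "consistency") {
    icc_s <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo_s <- (fl - 1) / (fl + k - 1)
    up_s <- (fu - 1) / (fu + k - 1)
  } else { # two-way agreement (Shrout-Fleiss ICC(2,1); Satterthwaite CI)
    icc_s <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * icc_s / (n * (1 - icc_s))
    b <- 1 + k * icc_s * (n - 1) / (n * (1 - icc_s))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo_s <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    up_s <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }

  if (unit == "average") {
    sb <- function(r) r * k / (1 + (k - 1) * r) # Spearman-Brown step-up
    icc_v <- sb(icc_s); lo <- sb(lo_s); up <- sb(up_s)
  } else {
    icc_v <- icc_s; lo <- lo_s; up <- up_s
  }
  status <- "ok"
  icc_out <- icc_v
  if (!is.finite(icc_v)) {
    status <- "undefined"
  } else if (icc_v < 0) {
    icc_out <- 0
    status <- "clipped-negative"
  }
  tibble::tibble(model = model, type = type, unit = unit, n = n, k = k,
                 icc = icc_out, icc_raw = icc_v,
                 lower = lo, upper = up, status = status)
}

#' Assemble a QA/QC report bundle
#'
#' For each fit, writes per-analyte artifacts into `dir`: the coefficient
#' table (CSV), fit statistics and LOQ estimates (JSON + CSV), the standard
#' curve plot with its band and blank line, the residual-vs-fitted plot
#' with exceedances labeled, and a normal QQ plot of standardized
#' residuals. Flagged points are drawn as empty circles and never enter
#' the fitted curve. A machine-readable `summary.json` covering all
#' analytes is written alongside.
#'
#' @param fits `curve_fit` or list of them.
#' @param loqs Optional `loq_estimate`, list of them (one per fit), or a
#'   list of such lists (several methods per fit).
#' @param dir Output directory (created if needed).
#' @param cutoff Outlier cutoff for the residual plot and outlier table.
#' @param band Band type for the curve plot.
#' @param device Plot file device, `"pdf"` (default) or `"png"`.
#' @return Invisibly, a list with `summary` (per-analyte tibble of fit
#'   statistics), `coefficients`, `outliers`, `loq` tibbles and the paths
#'   written.
#' @export
qc_report <- function(fits, loqs = NULL, dir, cutoff = 2,
                      band = "confidence", device = c("pdf", "png")) {
  if (inherits(fits, "curve_fit")) fits <- list(fits)
  if (!length(fits)) {
    rlang::abort("at least one fit is required", class = "beadcal_input_error")
  }
  device <- match.arg(device)
  if (inherits(loqs, "loq_estimate")) loqs <- list(loqs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  coefs <- summary_coefficients(fits)
  stats_tbl <- purrr::map_dfr(fits, function(f) {
    if (!f$converged) {
      return(tibble::tibble(plate_id = f$plate_id, analyte = f$analyte,
                            status = "fit-failure"))
    }
    dplyr::bind_cols(
      tibble::tibble(plate_id = f$plate_id, analyte = f$analyte,
                     status = "ok", bkg_method = f$bkg_method,
                     blank_gm = f$bkg_value, sigma = f$sigma),
      fit_statistics(f)
    )
  })
  outliers <- purrr::map_dfr(fits, function(f) {
    if (f$converged) get_outliers(f, cutoff) else NULL
  })
  loq_tbl <- NULL
  if (!is.null(loqs)) {
    loq_tbl <- purrr::imap_dfr(loqs, function(l, i) {
      f <- fits[[min(i, length(fits))]]
      items <- if (inherits(l, "loq_estimate")) list(l) else l
      purrr::map_dfr(items, tidy.loq_estimate) |>
        dplyr::mutate(plate_id = f$plate_id, analyte = f$analyte,
                      .before = 1)
    })
  }

  utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tbl, file.path(dir, "fit_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(outliers, file.path(dir, "outliers.csv"),
                   row.names = FALSE)
  if (!is.null(loq_tbl)) {
    utils::write.csv(loq_tbl, file.path(dir, "loq.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(statistics = stats_tbl, coefficients = coefs,
         outliers = outliers, loq = loq_tbl),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )

  paths <- c("coefficients.csv", "fit_statistics.csv", "outliers.csv",
             if (!is.null(loq_tbl)) "loq.csv", "summary.json")
  for (f in fits) {
    if (!f$converged) next
    tag <- paste0(gsub("[^A-Za-z0-9_-]", "_", f$analyte), "_",
                  gsub("[^A-Za-z0-9_-]", "_", f$plate_id))
    figs <- list(curve = plot_standard_curve(f, band = band),
                 resid = plot_residuals(f, cutoff = cutoff),
                 qq = plot_qq(f))
    for (nm in names(figs)) {
      path <- file.path(dir, paste0(tag, "_", nm, ".", device))
      if (device == "pdf") {
        grDevices::pdf(path, width = 6, height = 4.5)
      } else {
        grDevices::png(path, width = 720, height = 540)
      }
      print(figs[[nm]])
      grDevices::dev.off()
      paths <- c(paths, basename(path))
    }
  }
  invisible(list(summary = stats_tbl, coefficients = coefs,
                 outliers = outliers, loq = loq_tbl,
                 dir = dir, files = paths))
}
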