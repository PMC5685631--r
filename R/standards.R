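#' Coerce a data frame to the standard-well layout
#'
#' beadcal works on long-format well records with one row per
#' (plate, well, analyte): the layout most plate readers export after
#' reshaping. The canonical columns are `plate_id`, `well`, `analyte`,
#' `sample`, `mfi` (natural scale) and, for standards, `expected_conc`
#' (natural scale). `as_standard_table()` renames columns according to a
#' mapping, adds a logical `flagged` column when absent, and validates the
#' result. Blank-control tables use the same layout without `expected_conc`.
#'
#' @param data A data frame.
#' @param cols Named list/vector mapping canonical names to the column names
#'   in `data`, e.g. `list(mfi = "median", expected_conc = "ec")`. Canonical
#'   names already present are kept as is.
#' @param require_conc Require a positive `expected_conc` column (standards)
#'   or not (blanks/tests).
#' @return A tibble with canonical columns and a `flagged` column.
#' @export
as_standard_table <- function(data, cols = list(), require_conc = TRUE) {
  stopifnot(is.data.frame(data))
  out <- tibble::as_tibble(data)
  for (canon in names(cols)) {
    src <- cols[[canon]]
    if (!src %in% names(out)) {
      rlang::abort(paste0("mapped column '", src, "' not found"),
                   class = "beadcal_input_error")
    }
    names(out)[names(out) == src] <- canon
  }
  needed <- c("plate_id", "well", "analyte", "sample", "mfi")
  if (require_conc) needed <- c(needed, "expected_conc")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    rlang::abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
                 class = "beadcal_input_error")
  }
  if (!"flagged" %in% names(out)) out$flagged <- FALSE
  key <- paste(out$plate_id, out$well, out$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort("(plate_id, well, analyte) must uniquely identify a record",
                 class = "beadcal_input_error")
  }
  if (require_conc && any(!is.na(out$expected_conc) & out$expected_conc <= 0)) {
    rlang::abort("expected_conc must be > 0 for standard wells",
                 class = "beadcal_input_error")
  }
  out
}

#' Geometric mean
#'
#' Geometric mean of strictly positive values, `exp(mean(log(x)))`; the
#' summary used for replicate blank-control MFIs.
#'
#' @param values Numeric vector, all `> 0`, nonempty. `NA`s are dropped.
#' @return A positive scalar.
#' @examples
#' geometric_mean(c(50, 200)) # 100
#' @export
geometric_mean <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    rlang::abort("geometric mean of an empty set is undefined",
                 class = "beadcal_input_error")
  }
  if (any(values <= 0)) {
    rlang::abort("geometric mean requires strictly positive values",
                 class = "beadcal_input_error")
  }
  exp(mean(log(values)))
}

#' Serial-dilution step of a standard series
#'
#' Infers the dilution factor as the median ratio of consecutive distinct
#' sorted expected concentrations (2 for a 1:2 series).
#'
#' @param expected_conc Positive concentrations of the standard wells.
#' @return Scalar dilution factor (> 1).
#' @export
infer_dilution_factor <- function(expected_conc) {
  u <- sort(unique(expected_conc[expected_conc > 0]), decreasing = TRUE)
  if (length(u) < 2) {
    rlang::abort("need at least two distinct concentrations to infer a dilution factor",
                 class = "beadcal_input_error")
  }
  stats::median(u[-length(u)] / u[-1])
}

#' Apply a blank-control background treatment
#'
#' Adjusts a standard table for background noise before curve fitting, using
#' the geometric mean (GM) of the blank-control MFIs. Four methods:
#'
#' * `ignore` — blanks are disregarded; the table is returned unchanged.
#' * `subtract` — the blank GM is subtracted from every MFI; wells whose
#'   adjusted MFI is `<= 0` are excluded (reason
#'   `"nonpositive-after-subtract"`) because their log10 is undefined.
#' * `include` — one extra standard point is appended with MFI equal to the
#'   blank GM and expected concentration equal to the minimum standard
#'   concentration divided by the dilution factor.
#' * `constraint` — the table is unchanged but the fitter is instructed to
#'   fix the lower-asymptote coefficient at `log10(GM)`.
#'
#' @param std Standard table (see [as_standard_table()]).
#' @param blanks Blank table (same layout, no `expected_conc`); required for
#'   every method except `ignore`.
#' @param method One of `"ignore"`, `"subtract"`, `"include"`,
#'   `"constraint"`.
#' @param dilution_factor Serial-dilution factor used by `include`; inferred
#'   from the standards via [infer_dilution_factor()] when `NULL`.
#' @return A list of class `bkg_adjusted`: `standards` (tibble with columns
#'   `mfi_adj` and `exclude_reason`), `method`, `blank_gm` (natural MFI
#'   scale, `NA` for `ignore` without blanks) and `constraint_log10` (the
#'   fixed lower asymptote, or `NA`).
#' @export
apply_background <- function(std, blanks = NULL,
                             method = c("ignore", "subtract", "include", "constraint"),
                             dilution_factor = NULL) {
  method <- match.arg(method)
  std <- as_standard_table(std)
  gm <- NA_real_
  if (!is.null(blanks)) {
    blanks <- as_standard_table(blanks, require_conc = FALSE)
    gm <- geometric_mean(blanks$mfi)
  } else if (method != "ignore") {
    rlang::abort(paste0("background method '", method, "' requires blank controls"),
                 class = "beadcal_input_error")
  }
  out <- std
  out$mfi_adj <- out$mfi
  out$exclude_reason <- NA_character_
  constraint <- NA_real_
  if (method == "subtract") {
    out$mfi_adj <- out$mfi - gm
    bad <- out$mfi_adj <= 0
    out$exclude_reason[bad] <- "nonpositive-after-subtract"
  } else if (method == "include") {
    if (is.null(dilution_factor)) {
      dilution_factor <- infer_dilution_factor(out$expected_conc)
    }
    extra <- out[which.min(out$expected_conc), ]
    extra$well <- "BKG"
    extra$sample <- "background"
    extra$mfi <- gm
    extra$mfi_adj <- gm
    extra$expected_conc <- min(out$expected_conc) / dilution_factor
    extra$flagged <- FALSE
    extra$exclude_reason <- NA_character_
    out <- dplyr::bind_rows(out, extra)
  } else if (method == "constraint") {
    constraint <- log10(gm)
  }
  nonpos <- is.na(out$exclude_reason) & out$mfi_adj <= 0
  out$exclude_reason[nonpos] <- "nonpositive-mfi"
  structure(
    list(standards = out, method = method, blank_gm = gm,
         constraint_log10 = constraint),
    class = "bkg_adjusted"
  )
}
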