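# shared fixtures: hand-built standard tables and curve fits

make_std <- function(x, y, plate = "p1", analyte = "a1") {
  tibble::tibble(
    plate_id = plate,
    well = paste0(LETTERS[((seq_along(x) - 1) %/% 12) + 1],
                  ((seq_along(x) - 1) %% 12) + 1),
    analyte = analyte,
    sample = paste0("Standard", seq_along(x)),
    mfi = 10^y,
    expected_conc = 10^x,
    flagged = FALSE
  )
}

make_blanks <- function(mfi, plate = "p1", analyte = "a1") {
  tibble::tibble(
    plate_id = plate,
    well = paste0("H", seq_along(mfi)),
    analyte = analyte,
    sample = paste0("Background", seq_along(mfi)),
    mfi = mfi,
    flagged = FALSE
  )
}

# noise-free standards from a model over the 17-point 1:2 design
noiseless_std <- function(model, top = 1e4, n_dil = 16, factor = 2,
                          dup_top = TRUE) {
  conc <- top / factor^(seq_len(n_dil) - 1)
  if (dup_top) conc <- c(conc, top)
  x <- log10(conc)
  make_std(x, eval_curve(model, x))
}

# a curve_fit built by hand: fixed parameters, supplied covariance and
# residual scale; for delta-method / band oracles that need exact inputs
fake_fit <- function(model, vcov = NULL, sigma = 0, df = 10,
                     xs = seq(-1, 3, length.out = 9),
                     bkg_method = "ignore", bkg_value = NA_real_) {
  free <- names(model$params)
  if (is.null(vcov)) {
    vcov <- matrix(0, length(free), length(free),
                   dimnames = list(free, free))
  }
  y <- eval_curve(model, xs)
  data <- tibble::tibble(
    plate_id = "p1", well = paste0("A", seq_along(xs)), analyte = "a1",
    sample = paste0("Standard", seq_along(xs)),
    mfi = 10^y, expected_conc = 10^xs, flagged = FALSE,
    mfi_adj = 10^y, exclude_reason = NA_character_,
    x = xs, y = y, used = TRUE,
    .fitted = y, .resid = 0, .std_resid = 0
  )
  structure(
    list(data = data,
         excluded = tibble::tibble(plate_id = character(), well = character(),
                                   analyte = character(), reason = character()),
         bkg_method = bkg_method, bkg_value = bkg_value,
         constraint_log10 = NA_real_,
         fallback_log = tibble::tibble(model_id = model$model_id,
                                       converged = TRUE, message = "fixed"),
         plate_id = "p1", analyte = "a1",
         converged = TRUE, model = model, coef = model$params,
         vcov = vcov, free = free, sigma = sigma, df = df,
         n_used = length(xs)),
    class = "curve_fit"
  )
}

xponent_fixture <- function() {
  system.file("extdata", "xponent_synthetic.csv", package = "beadcal")
}
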