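#' Configure a synthetic assay plate
#'
#' Describes one simulated analyte on a 96-well plate: a 4PL truth curve,
#' a serial-dilution standard series with the top dilution optionally
#' duplicated, Gaussian noise on log10 MFI, optional injected outliers
#' (noise SD multiplied, default doubled), optional missing design points,
#' and replicate blank wells drawn lognormally around the lower asymptote.
#'
#' Default truth (`b = -1.2, c = 1.1, d = 3.2, e = 0.9`, noise SD 0.05 on
#' log10 MFI, top concentration 10000 with 16 two-fold dilutions) emulates
#' a realistic cytokine panel curve spanning about 4.5 decades; these are
#' fixture choices of this package, documented in the methods vignette.
#'
#' @param b,c,d,e True 4PL parameters (log10/log10 parameterization; see
#'   [ll4_model()]).
#' @param n_dilutions Number of serial dilutions.
#' @param dilution_factor Serial-dilution factor (2 = 1:2 series).
#' @param top_conc Concentration of the first (highest) dilution.
#' @param duplicate_top Duplicate the top dilution (17 designed points for
#'   16 dilutions)?
#' @param noise_sd SD of Gaussian noise on log10 MFI.
#' @param outlier_idx Designed-point indices (1-based, top duplicate last)
#'   whose noise SD is multiplied by `outlier_mult`.
#' @param outlier_mult Outlier noise multiplier (default 2).
#' @param missing_idx Designed-point indices removed from the output.
#' @param n_blanks Number of blank-control wells.
#' @param blank_meanlog10,blank_sdlog10 Mean and SD of log10 blank MFI;
#'   mean defaults to the lower asymptote `c`.
#' @param plate_id,analyte Identifiers stamped on the generated records.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(b = -1.2, c = 1.1, d = 3.2, e = 0.9,
                            n_dilutions = 16, dilution_factor = 2,
                            top_conc = 1e4, duplicate_top = TRUE,
                            noise_sd = 0.05, outlier_idx = integer(),
                            outlier_mult = 2, missing_idx = integer(),
                            n_blanks = 2, blank_meanlog10 = c,
                            blank_sdlog10 = 0.05,
                            plate_id = "plate_1", analyte = "analyte_1") {
  n_points <- n_dilutions + as.integer(duplicate_top)
  outlier_idx <- as.integer(outlier_idx)
  missing_idx <- as.integer(missing_idx)
  if (length(intersect(outlier_idx, missing_idx))) {
    rlang::abort("outlier and missing indices must be disjoint",
                 class = "beadcal_input_error")
  }
  if (length(c(outlier_idx, missing_idx)) &&
      any(c(outlier_idx, missing_idx) < 1 |
          c(outlier_idx, missing_idx) > n_points)) {
    rlang::abort("outlier/missing indices out of range",
                 class = "beadcal_input_error")
  }
  structure(
    list(b = b, c = c, d = d, e = e, n_dilutions = n_dilutions,
         dilution_factor = dilution_factor, top_conc = top_conc,
         duplicate_top = duplicate_top, noise_sd = noise_sd,
         outlier_idx = outlier_idx, outlier_mult = outlier_mult,
         missing_idx = missing_idx, n_blanks = n_blanks,
         blank_meanlog10 = blank_meanlog10, blank_sdlog10 = blank_sdlog10,
         plate_id = plate_id, analyte = analyte, n_points = n_points),
    class = "scenario_config"
  )
}

well_names <- function(n, offset = 0) {
  idx <- seq_len(n) + offset
  paste0(LETTERS[((idx - 1) %/% 12) + 1], ((idx - 1) %% 12) + 1)
}

#' Generate a synthetic plate
#'
#' Simulates standards, blanks and (optionally) test wells for one analyte
#' under a [scenario_config()]. Standard MFIs are
#' `10^(LL4(log10 conc) + eps)` with `eps ~ N(0, sd)` (outlier points use
#' `sd * outlier_mult`); expected concentrations form the exact geometric
#' series `top / factor^(k-1)`; listed missing points are absent from the
#' output; blanks are lognormal around `10^blank_meanlog10`. Fully
#' reproducible from `seed`.
#'
#' @param config A `scenario_config`.
#' @param seed Integer seed for the plate's RNG (a single seed governs the
#'   whole plate).
#' @param n_tests Number of additional test wells, with true log10
#'   concentrations drawn uniformly over the central standard range.
#' @return List with `standards`, `blanks`, `tests` (tibbles in the
#'   standard-well layout; `tests` carries a hidden true concentration in
#'   `true_log10_conc`) and `truth` (the generating [ll4_model()] plus
#'   config).
#' @export
generate_plate <- function(config, seed = NULL, n_tests = 0) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  truth <- ll4_model(cf$b, cf$c, cf$d, cf$e)
  k <- seq_len(cf$n_dilutions)
  conc <- cf$top_conc / cf$dilution_factor^(k - 1)
  if (cf$duplicate_top) conc <- c(conc, cf$top_conc)
  n <- length(conc)
  sd_vec <- rep(cf$noise_sd, n)
  sd_vec[cf$outlier_idx] <- cf$noise_sd * cf$outlier_mult
  eps <- stats::rnorm(n, 0, sd_vec)
  y <- eval_curve(truth, log10(conc)) + eps
  std <- tibble::tibble(
    plate_id = cf$plate_id,
    well = well_names(n),
    analyte = cf$analyte,
    sample = paste0("Standard", c(k, if (cf$duplicate_top) 1L)),
    mfi = 10^y,
    expected_conc = conc,
    flagged = FALSE,
    is_outlier = seq_len(n) %in% cf$outlier_idx
  )
  if (length(cf$missing_idx)) std <- std[-cf$missing_idx, ]

  blanks <- tibble::tibble(
    plate_id = cf$plate_id,
    well = well_names(cf$n_blanks, offset = n),
    analyte = cf$analyte,
    sample = paste0("Background", seq_len(cf$n_blanks)),
    mfi = 10^stats::rnorm(cf$n_blanks, cf$blank_meanlog10, cf$blank_sdlog10),
    flagged = FALSE
  )

  tests <- NULL
  if (n_tests > 0) {
    xr <- range(log10(conc))
    xt <- stats::runif(n_tests, xr[1] + 0.1 * diff(xr), xr[2] - 0.1 * diff(xr))
    yt <- eval_curve(truth, xt) + stats::rnorm(n_tests, 0, cf$noise_sd)
    tests <- tibble::tibble(
      plate_id = cf$plate_id,
      well = if (n + cf$n_blanks + n_tests <= 96) {
        well_names(n_tests, offset = n + cf$n_blanks)
      } else {
        paste0("T", seq_len(n_tests)) # virtual wells beyond one physical plate
      },
      analyte = cf$analyte,
      sample = paste0("S", seq_len(n_tests)),
      mfi = 10^yt,
      flagged = FALSE,
      true_log10_conc = xt
    )
  }
  list(standards = std, blanks = blanks, tests = tests,
       truth = list(model = truth, config = cf))
}

#' Preset toy scenarios
#'
#' Four named scenario configurations mirroring common plate pathologies on
#' a 16-dilution 1:2 series with duplicated top (17 designed points) and
#' two blanks:
#'
#' * `analyte1` — all 17 points observed, no outliers.
#' * `analyte2` — 7 points missing (the most dilute wells), 10 observed.
#' * `analyte3` — 7 missing and 1 injected outlier among the 10 observed.
#' * `analyte4` — all 17 observed, 2 injected outliers.
#'
#' Outlier points have their noise SD doubled relative to the rest of the
#' plate.
#'
#' @return Named list of four [scenario_config()]s.
#' @export
scenario_presets <- function() {
  list(
    analyte1 = scenario_config(plate_id = "plate_1", analyte = "analyte_1"),
    analyte2 = scenario_config(plate_id = "plate_1", analyte = "analyte_2",
                               missing_idx = 10:16),
    analyte3 = scenario_config(plate_id = "plate_1", analyte = "analyte_3",
                               missing_idx = 10:16, outlier_idx = 5L),
    analyte4 = scenario_config(plate_id = "plate_1", analyte = "analyte_4",
                               outlier_idx = c(5L, 9L))
  )
}
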