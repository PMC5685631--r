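Package: beadcal
Title: Calibration and Quality Control for Multiplex Bead-Based Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calibrating multiplex bead-based immunoassays (for
    example Luminex xMAP panels) from raw median fluorescence intensities.
    Fits five- and four-parameter log-logistic and exponential standard
    curves on log10-transformed data with sequential model fallback, offers
    four treatments of blank-control background noise, estimates limits of
    quantification by derivative, interval and coefficient-of-variation
    methods, inverse-predicts test-sample concentrations with delta-method
    standard errors, and supports assay quality control through outlier
    flagging on standardized residuals, lack-of-fit testing, intraclass
    correlation and report generation. Includes an importer for sectioned
    xPONENT 3.1 CSV exports and a seeded synthetic-plate generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
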