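test_that("outlier detection flags all and only cutoff exceedances", {
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(m)
  exact <- fit_standard_curve(std, model_order = "LL4")
  expect_identical(nrow(get_outliers(exact)), 0L) # perfect fit: none

  # displace one point by ~10 sigma in an otherwise clean plate
  set.seed(101)
  noisy <- std
  noisy$mfi <- noisy$mfi * 10^rnorm(nrow(noisy), 0, 0.05)
  noisy$mfi[8] <- noisy$mfi[8] * 10^0.5
  fit <- fit_standard_curve(noisy, model_order = "LL4")
  out <- get_outliers(fit, cutoff = 2)
  expect_true(noisy$well[8] %in% out$well)
  expect_true(all(abs(out$std_resid) > 2))
  # all exceedances are returned, none missed
  manual <- fit$data$well[fit$data$used & abs(fit$data$.std_resid) > 2]
  expect_setequal(out$well, manual)

  # cutoff monotonicity: a larger cutoff returns a subset
  for (cut in c(1, 1.5, 2.5, 3.5)) {
    expect_true(all(get_outliers(fit, cut + 0.5)$well %in%
                      get_outliers(fit, cut)$well))
  }
  expect_identical(nrow(get_outliers(fit, cutoff = Inf)), 0L)
})

test_that("injected outliers are flagged far more often than clean wells", {
  pres <- scenario_presets()
  flags_out <- 0; n_out <- 0; flags_clean <- 0; n_clean <- 0
  for (i in 1:100) {
    pl <- generate_plate(pres$analyte4, seed = 7000 + i)
    f <- fit_standard_curve(pl$standards, pl$blanks, "ignore",
                            model_order = "LL4")
    if (!f$converged) next
    out <- get_outliers(f, 2)
    inj <- pl$standards$well[pl$standards$is_outlier]
    n_out <- n_out + length(inj)
    n_clean <- n_clean + sum(!pl$standards$is_outlier)
    flags_out <- flags_out + sum(out$well %in% inj)
    flags_clean <- flags_clean + sum(!out$well %in% inj)
  }
  rate_out <- flags_out / n_out
  rate_clean <- flags_clean / n_clean
  expect_gt(rate_out, 3 * rate_clean)
  expect_gt(rate_out, 0.1)
})

test_that("flagging a non-outlier in clean data barely moves the fit", {
  set.seed(102)
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(m)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.03)
  fit <- fit_standard_curve(std, model_order = "LL4")
  keep <- get_outliers(fit, 2)
  clean_well <- setdiff(std$well, keep$well)[5]
  rf <- flag_and_refit(std, clean_well, model_order = "LL4")
  shift <- abs(rf$fit$coef - fit$coef)
  se <- sqrt(diag(fit$vcov))[names(shift)]
  expect_true(all(shift < se))
})

test_that("ICC matches its definition in exact and simulated cases", {
  # duplicated identical columns: perfect reliability
  subj <- rnorm(20)
  perfect <- cbind(subj, subj, subj)
  for (model in c("oneway", "twoway")) {
    r <- intra_icc(perfect, model = model)
    expect_equal(r$icc, 1, tolerance = 1e-12)
  }
  # consistency is invariant to a per-column constant shift
  shifted <- cbind(subj, subj + 5)
  rc <- intra_icc(shifted, model = "twoway", type = "consistency")
  expect_equal(rc$icc, 1, tolerance = 1e-12)
  # agreement is not
  ra <- intra_icc(shifted, model = "twoway", type = "agreement")
  expect_lt(ra$icc, 1)

  expect_error(intra_icc(matrix(rnorm(2), 2, 1)),
               class = "beadcal_input_error")

  # recovery: truth tau^2/(tau^2+sigma^2) = 0.5
  set.seed(103)
  est <- replicate(500, {
    mu <- rnorm(30, sd = 1)
    m <- matrix(rnorm(30 * 3, mean = mu, sd = 1), 30, 3)
    intra_icc(m, model = "oneway", unit = "single")$icc
  })
  expect_equal(mean(est), 0.5, tolerance = 0.05)
  # F-based CI is ordered around the estimate
  r <- intra_icc(matrix(rnorm(60, mean = rep(rnorm(20), 3)), 20, 3),
                 model = "twoway", type = "agreement")
  expect_true(r$lower <= r$icc_raw && r$icc_raw <= r$upper)
})

test_that("the QC report writes every section and round-trips its numbers", {
  set.seed(104)
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(m)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.05)
  blanks <- make_blanks(c(11, 13))
  fit <- fit_standard_curve(std, blanks, "subtract", model_order = "LL4")
  loqs <- list(list(loq_derivative(fit), loq_cv(fit, 0.30)))

  dir <- withr::local_tempdir()
  rep <- qc_report(fit, loqs, dir = dir)
  for (f in c("coefficients.csv", "fit_statistics.csv", "outliers.csv",
              "loq.csv", "summary.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  expect_length(list.files(dir, pattern = "\\.pdf$"), 3) # curve, resid, qq

  # the report's numbers equal direct API calls
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$statistics$r2, fit_statistics(fit)$r2, tolerance = 1e-9)
  coefs <- utils::read.csv(file.path(dir, "coefficients.csv"))
  expect_equal(coefs$estimate, summary_coefficients(fit)$estimate,
               tolerance = 1e-9)

  expect_error(qc_report(list(), dir = dir), class = "beadcal_input_error")
})
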