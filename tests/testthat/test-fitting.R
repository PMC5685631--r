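test_that("noise-free data from each model family is recovered exactly", {
  truth4 <- ll4_model(-1.2, 1.1, 3.2, 0.8)
  std <- noiseless_std(truth4)
  fit <- fit_standard_curve(std, model_order = "LL4")
  expect_true(fit$converged)
  expect_equal(unname(fit$coef[c("b", "c", "d", "e")]),
               unname(truth4$params), tolerance = 1e-6)
  expect_equal(fit_statistics(fit)$r2, 1, tolerance = 1e-8)

  # LL5 nests the LL4 truth and recovers the same curve
  fit5 <- fit_standard_curve(std, model_order = "LL5")
  expect_true(fit5$converged)
  expect_equal(eval_curve(fit5$model, std |> dplyr::pull(expected_conc) |> log10()),
               log10(std$mfi), tolerance = 1e-5)

  # EXP truth recovered by the EXP branch
  tE <- exp_model(a0 = 0.8, b = 0.45)
  stdE <- make_std(seq(0, 3, length.out = 8), eval_curve(tE, seq(0, 3, length.out = 8)))
  fitE <- suppressWarnings(fit_standard_curve(stdE, model_order = "EXP")) # exact fit
  expect_equal(unname(fitE$coef), unname(tE$params), tolerance = 1e-9)
})

test_that("sequential fallback is attempted in order and logged", {
  truth <- ll4_model(-1.2, 1.1, 3.2, 0.8)
  x <- seq(-0.5, 3.5, length.out = 5) # 5 points: too few for LL5 (needs 6)
  std <- make_std(x, eval_curve(truth, x))
  fit <- fit_standard_curve(std, model_order = c("LL5", "LL4", "EXP"))
  expect_true(fit$converged)
  expect_identical(fit$model$model_id, "LL4")
  expect_identical(fit$fallback_log$model_id, c("LL5", "LL4"))
  expect_identical(fit$fallback_log$converged, c(FALSE, TRUE))

  # total failure returns a non-converged fit carrying the log, not an error
  tiny <- make_std(c(0, 1), c(1.5, 2.5))
  bad <- fit_standard_curve(tiny, model_order = c("LL4", "EXP"))
  expect_false(bad$converged)
  expect_identical(bad$fallback_log$model_id, c("LL4", "EXP"))
  expect_false(any(bad$fallback_log$converged))
  expect_error(fit_statistics(bad), class = "beadcal_fit_error")
})

test_that("fitting after subtract equals fitting the manually shifted table", {
  set.seed(61)
  truth <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(truth)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.05)
  blanks <- make_blanks(c(9, 11))
  gm <- geometric_mean(blanks$mfi)

  f_sub <- fit_standard_curve(std, blanks, "subtract", model_order = "LL4")
  shifted <- std
  shifted$mfi <- shifted$mfi - gm
  shifted <- shifted[shifted$mfi > 0, ]
  f_man <- fit_standard_curve(shifted, model_order = "LL4")
  expect_identical(f_sub$n_used, f_man$n_used)
  expect_equal(f_sub$coef, f_man$coef, tolerance = 1e-12)
  expect_equal(f_sub$vcov, f_man$vcov, tolerance = 1e-12)
})

test_that("constraint fixes the lower asymptote and shrinks the covariance", {
  set.seed(62)
  truth <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(truth)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.03)
  blanks <- make_blanks(c(12, 13.2))
  fit <- fit_standard_curve(std, blanks, "constraint", model_order = "LL4")
  expect_true(fit$converged)
  expect_setequal(fit$free, c("b", "d", "e"))
  expect_identical(dim(fit$vcov), c(3L, 3L))
  expect_equal(unname(fit$model$params["c"]),
               log10(geometric_mean(blanks$mfi)))
  # covariance is symmetric PSD
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
  # the fixed coefficient is absent from the tested coefficients
  expect_false("c" %in% summary_coefficients(fit)$term)
})

test_that("flagged points are excluded from the refit objective", {
  set.seed(63)
  truth <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  std <- noiseless_std(truth)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.05)
  fit0 <- fit_standard_curve(std, model_order = "LL4")

  rf <- flag_and_refit(std, wells = std$well[c(3, 7)], model_order = "LL4")
  expect_identical(rf$fit$n_used, fit0$n_used - 2L)
  expect_true(all(rf$fit$data$flagged[c(3, 7)]))
  expect_true(all(!rf$fit$data$used[c(3, 7)]))
  expect_true(all(c(std$well[3], std$well[7]) %in% rf$fit$excluded$well))

  # flagging nothing reproduces the same optimum
  rf0 <- flag_and_refit(std, wells = character(0), model_order = "LL4")
  expect_equal(rf0$fit$coef, fit0$coef, tolerance = 1e-10)

  # idempotent on an already-flagged set
  rf2 <- flag_and_refit(rf$standards, wells = std$well[c(3, 7)],
                        model_order = "LL4")
  expect_equal(rf2$fit$coef, rf$fit$coef, tolerance = 1e-12)
  expect_identical(rf2$fit$n_used, rf$fit$n_used)

  expect_error(flag_and_refit(std, wells = "Z99"),
               class = "beadcal_input_error")
})

test_that("fit statistics follow their stated formulas", {
  # EXP on 5 hand-made points: compare against direct arithmetic from lm
  x <- c(0, 0.5, 1, 1.5, 2)
  y <- c(1.02, 1.21, 1.38, 1.64, 1.81)
  std <- make_std(x, y)
  fit <- fit_standard_curve(std, model_order = "EXP")
  st <- fit_statistics(fit)

  lmf <- lm(y ~ x)
  rss <- sum(resid(lmf)^2)
  tss <- sum((y - mean(y))^2)
  n <- 5; p <- 2
  expect_equal(st$r2, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(st$adjusted_r2, 1 - (1 - st$r2) * (n - 1) / (n - p),
               tolerance = 1e-12)
  expect_equal(st$aic, n * log(2 * pi) + n * log(rss / n) + n + 2 * (p + 1),
               tolerance = 1e-12)
  # the stated convention coincides with R's Gaussian AIC for this model
  expect_equal(st$aic, AIC(lmf), tolerance = 1e-9)

  # all-identical responses make R^2 undefined, not 0/0
  flat <- suppressWarnings(fit_standard_curve(make_std(x, rep(1.5, 5)), model_order = "EXP"))
  expect_true(is.na(fit_statistics(flat)$r2))
})

test_that("coefficient summaries use the t distribution on residual df", {
  m <- exp_model(a0 = 1, b = 1)
  fit <- fake_fit(m, vcov = diag(c(0.25, 0.25)) |>
                    `dimnames<-`(list(c("a0", "b"), c("a0", "b"))),
                  sigma = 0.1, df = 10)
  fit$coef <- c(a0 = 1, b = 1)
  tab <- summary_coefficients(fit)
  expect_equal(tab$statistic, c(2, 2))
  # two-sided p frozen from an independent t-distribution evaluation
  expect_equal(tab$p_value, rep(0.07338803477074037, 2), tolerance = 1e-9)

  # a failed fit yields a status-only row
  tiny <- make_std(c(0, 1), c(1.5, 2.5))
  bad <- fit_standard_curve(tiny, model_order = "LL4")
  row <- summary_coefficients(bad)
  expect_identical(row$status, "fit-failure")
  expect_true(is.na(row$estimate))
})

test_that("the Neill test detects misfit and degrades gracefully", {
  truth <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  x17 <- log10(1e4 / 2^(0:16))[1:17]
  x <- rep(x17, 2)

  # no replicated design points -> pure error not estimable
  set.seed(71)
  single <- make_std(x17, eval_curve(truth, x17) + rnorm(17, 0, 0.05))
  f_single <- fit_standard_curve(single, model_order = "LL4")
  expect_identical(neill_test(f_single)$status, "undefined")

  # power: a sinusoidal departure from the 4PL is flagged in >= 90% of
  # replicated-design simulations
  set.seed(72)
  rej <- vapply(1:200, function(i) {
    y <- eval_curve(truth, x) + 0.1 * sin(pi * x) + rnorm(34, 0, 0.05)
    f <- fit_standard_curve(make_std(x, y), model_order = "LL4")
    f$converged && neill_test(f)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.90)
})
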