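test_that("bands collapse without uncertainty and prediction contains confidence", {
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  exact <- fake_fit(m) # sigma = 0, zero covariance
  xg <- seq(-1, 3, length.out = 25)
  cb <- curve_band(exact, xg, band = "confidence")
  pb <- curve_band(exact, xg, band = "prediction")
  expect_equal(cb$lower, cb$fit)
  expect_equal(cb$upper, cb$fit)
  expect_equal(pb$lower, pb$fit)

  set.seed(81)
  std <- noiseless_std(m)
  std$mfi <- std$mfi * 10^rnorm(nrow(std), 0, 0.05)
  fit <- fit_standard_curve(std, model_order = "LL4")
  cb <- curve_band(fit, xg, band = "confidence")
  pb <- curve_band(fit, xg, band = "prediction")
  expect_true(all(pb$lower < cb$lower))
  expect_true(all(pb$upper > cb$upper))
})

test_that("band half-width equals a hand-computed delta-method product", {
  m <- exp_model(a0 = 1, b = 0.5)
  vc <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
               dimnames = list(c("a0", "b"), c("a0", "b")))
  fit <- fake_fit(m, vcov = vc, sigma = 0.2, df = 7, xs = c(0, 1, 2))
  x0 <- 1.3
  g <- c(1, x0) # gradient of a0 + b x
  sef <- sqrt(drop(t(g) %*% vc %*% g))
  tq <- qt(0.975, 7)
  cb <- curve_band(fit, x0, band = "confidence")
  pb <- curve_band(fit, x0, band = "prediction")
  expect_equal(cb$upper - cb$fit, tq * sef, tolerance = 1e-12)
  expect_equal(pb$upper - pb$fit, tq * sqrt(0.2^2 + sef^2), tolerance = 1e-12)
})

test_that("derivative-method limits equal the LL4 closed-form bend points", {
  shift <- function(b) log10(2 + sqrt(3)) / abs(b)
  set.seed(82)
  for (i in 1:20) {
    b <- runif(1, -2.5, -0.4); e <- runif(1, 0, 1.5)
    fit <- fake_fit(ll4_model(b, 1, 3, e))
    l <- loq_derivative(fit)
    expect_identical(l$status, "ok")
    expect_equal(l$lloq, e - shift(b), tolerance = 1e-8)
    expect_equal(l$hloq, e + shift(b), tolerance = 1e-8)
    expect_equal(l$dynamic_range, l$hloq - l$lloq)
    # symmetric about e for the symmetric 4PL
    expect_equal((l$lloq + l$hloq) / 2, e, tolerance = 1e-8)
  }
  expect_identical(loq_derivative(fake_fit(exp_model(1, 0.5)))$status,
                   "not-applicable")
})

test_that("interval-method limits match an independent bisection oracle", {
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  vc <- diag(c(0.003, 0.002, 0.001, 0.002))
  dimnames(vc) <- list(c("b", "c", "d", "e"), c("b", "c", "d", "e"))
  fit <- fake_fit(m, vcov = vc, sigma = 0.05, df = 12)
  l <- loq_interval(fit, level = 0.95)
  expect_identical(l$status, "ok")

  # oracle: same statistical definition, re-derived by hand and solved by
  # plain bisection (no package band/root machinery)
  p <- m$params
  tq <- qt(0.975, 12)
  pred_bound <- function(x, sign) {
    g <- cbind(
      b = (p["d"] - p["c"]) * -(10^(p["b"] * (x - p["e"])) * log(10) * (x - p["e"])) /
        (1 + 10^(p["b"] * (x - p["e"])))^2,
      c = 1 - 1 / (1 + 10^(p["b"] * (x - p["e"]))),
      d = 1 / (1 + 10^(p["b"] * (x - p["e"]))),
      e = (p["d"] - p["c"]) * (10^(p["b"] * (x - p["e"])) * log(10) * p["b"]) /
        (1 + 10^(p["b"] * (x - p["e"])))^2
    )
    sef2 <- rowSums((g %*% vc) * g)
    yhat <- p["c"] + (p["d"] - p["c"]) / (1 + 10^(p["b"] * (x - p["e"])))
    unname(yhat + sign * tq * sqrt(0.05^2 + sef2))
  }
  bisect <- function(fun, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (fun(lo) * fun(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  c_up <- unname(p["c"] + tq * sqrt(vc["c", "c"]))
  d_lo <- unname(p["d"] - tq * sqrt(vc["d", "d"]))
  lloq_oracle <- bisect(function(x) pred_bound(x, -1) - c_up, -2, p[["e"]])
  hloq_oracle <- bisect(function(x) pred_bound(x, +1) - d_lo, p[["e"]], 4)
  expect_equal(l$lloq, lloq_oracle, tolerance = 1e-6)
  expect_equal(l$hloq, hloq_oracle, tolerance = 1e-6)

  # degenerate limit: with no uncertainty the bounds never cross the
  # asymptotes at finite x
  expect_identical(loq_interval(fake_fit(m))$status, "not-estimable")
  expect_identical(loq_interval(fake_fit(exp_model(1, 0.5)))$status,
                   "not-applicable")
})

test_that("concentration SEs propagate parameter uncertainty correctly", {
  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  # zero covariance, response error off -> SE exactly 0
  cs0 <- concentration_se(fake_fit(m), y = 2)
  expect_equal(cs0$se, 0)
  expect_equal(cs0$x_hat, as.numeric(inverse_curve(m, 2)))

  # near-asymptote response: slope vanishes, SE infinite
  vc <- diag(c(0.003, 0.002, 0.001, 0.002))
  dimnames(vc) <- list(c("b", "c", "d", "e"), c("b", "c", "d", "e"))
  fit <- fake_fit(m, vcov = vc, sigma = 0.05, df = 12)
  y_hi <- m$params[["c"]] + 0.99999 * (m$params[["d"]] - m$params[["c"]])
  expect_identical(concentration_se(fit, y_hi, slope_tol = 1e-4)$status,
                   "infinite")
  # out-of-range responses carry a side status
  cs <- concentration_se(fit, c(0.5, 2, 3.5))
  expect_identical(cs$status, c("below-range", "ok", "above-range"))

  # parametric bootstrap oracle: SD over parameter draws within 10%
  set.seed(83)
  y0 <- 2.4
  draws <- MASS::mvrnorm(2000, mu = m$params, Sigma = vc)
  xb <- apply(draws, 1, function(th) {
    mm <- ll4_model(th["b"], th["c"], th["d"], th["e"])
    as.numeric(inverse_curve(mm, y0, strict = FALSE))
  })
  boot_se <- sd(xb, na.rm = TRUE)
  delta_se <- concentration_se(fit, y0)$se
  expect_lt(abs(delta_se - boot_se) / boot_se, 0.10)
})

test_that("the CV formula behaves as printed and drives the CV-method limits", {
  expect_equal(cv_from_se(0), 0)
  expect_equal(cv_from_se(sqrt(log(1.09)) / log(10)), 0.30, tolerance = 1e-12)
  # frozen independent evaluation of the reference SE
  expect_equal(sqrt(log(1.09)) / log(10), 0.12749165279568803, tolerance = 1e-12)
  se <- seq(0, 0.5, length.out = 50)
  expect_true(all(diff(cv_from_se(se)) > 0)) # strictly increasing

  m <- ll4_model(-1.2, 1.1, 3.2, 0.9)
  vc <- diag(c(0.003, 0.002, 0.001, 0.002))
  dimnames(vc) <- list(c("b", "c", "d", "e"), c("b", "c", "d", "e"))
  fit <- fake_fit(m, vcov = vc, sigma = 0.05, df = 12)
  l <- loq_cv(fit, cv_cutoff = 0.30)
  expect_identical(l$status, "ok")
  expect_lt(l$lloq, l$hloq)

  # impossible cutoff: even the minimum CV exceeds it
  tight <- loq_cv(fit, cv_cutoff = 1e-6)
  expect_identical(tight$status, "not-estimable")
  expect_gt(tight$settings$min_cv, 1e-6)

  # shrinking the uncertainty widens the quantifiable range
  fit_small <- fake_fit(m, vcov = vc / 100, sigma = 0.005, df = 12)
  l_small <- loq_cv(fit_small, cv_cutoff = 0.30)
  expect_gt(l_small$dynamic_range, l$dynamic_range)
})
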