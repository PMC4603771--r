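test_that("a noiseless population is fitted back exactly", {
  p0 <- zero_noise_params(1)
  set.seed(10)
  feats <- sample_cycle(stats::runif(100, 5e4, 3e5), p0)
  fit <- fit_regressions(feats)
  td <- suppressWarnings(tidy(fit))  # perfect fit
  r <- prc1_params(1)$regression
  truth <- c(r$b1, r$b10, r$b2, r$b21, r$b4, r$b41, r$b43, r$b5, r$b52)
  expect_equal(unname(td$estimate), truth, tolerance = 1e-8)
  expect_true(all(fit$dispersion_sd < 1e-10))
})

test_that("coefficients are recovered within 3 SE from a stochastic population", {
  for (k in c(1, 2)) {
    p <- prc1_params(k)
    set.seed(50 + k)
    feats <- prc1dyn:::simulate_post_burnin(p, 2000)
    fit <- fit_regressions(feats, t1_link = p$regression$t1_link)
    td <- tidy(fit)
    r <- p$regression
    truth <- c(r$b1, r$b10, r$b2, r$b21, r$b4, r$b41, r$b43, r$b5, r$b52)
    z <- abs(td$estimate - truth) / td$std.error
    expect_lt(max(z), 3, label = paste("data set", k, "max z"))
    expect_lt(max(abs(fit$dispersion_sd / noise_sd(r) - 1)), 0.15)
  }
})

test_that("degenerate designs fail naming the offending equation", {
  feats <- sample_cycle(rep(1e5, 40), zero_noise_params(1))
  # constant X0 makes ln(a), hence every regressor, constant
  expect_error(fit_regressions(feats), "ln\\(a\\)|rank", ignore.case = TRUE)
  expect_error(fit_regressions(feats[1:10, ]), "at least 30")
})

test_that("fitted parameter objects can parameterise new simulations", {
  p <- prc1_params(1)
  set.seed(77)
  feats <- prc1dyn:::simulate_post_burnin(p, 1000)
  fit <- fit_regressions(feats)
  div <- estimate_division_asymmetry(feats)
  refit <- fitted_params(fit, div, data_set = NA)
  ped <- simulate_pedigree(refit, 4, seed = 1)
  expect_equal(nrow(ped), 31)
  refit_var <- fitted_params(fit, div, noise_convention = "var")
  expect_equal(noise_sd(refit_var$regression), noise_sd(refit$regression))
})

test_that("division asymmetry is recovered from the cv identity", {
  # Monte-Carlo: X2 lognormal (cv 0.3), U ~ Beta(29.29, 29.29), X0 = U X2
  set.seed(9)
  n <- 1e5
  X2 <- stats::rlnorm(n, log(2e5), sqrt(log(1 + 0.3^2)))
  U <- rbeta(n, 29.29, 29.29)
  feats <- tibble::tibble(X0 = U * X2, X2 = X2)
  est <- estimate_division_asymmetry(feats)
  expect_lt(abs(est$alpha / 29.29 - 1), 0.10)

  # degenerate X2: cv_U^2 reduces to cv_X0^2 exactly
  feats2 <- tibble::tibble(X0 = U[1:1000] * 2e5, X2 = rep(2e5, 1000))
  est2 <- estimate_division_asymmetry(feats2)
  cv0 <- sd(feats2$X0) / mean(feats2$X0)
  expect_equal(est2$cv_U2, cv0^2)

  # unidentifiable direction reports both cv values
  feats3 <- tibble::tibble(X0 = rep(1e5, 50), X2 = stats::rlnorm(50, log(2e5), 0.3))
  expect_error(estimate_division_asymmetry(feats3), "cv\\(X0\\)")
})

test_that("the cv identity holds across alpha and X2-dispersion settings", {
  set.seed(14)
  for (alpha in c(5, 100)) {
    for (cv2 in c(0.1, 0.3)) {
      n <- 2e5
      X2 <- stats::rlnorm(n, log(1e5), sqrt(log(1 + cv2^2)))
      U <- rbeta(n, alpha, alpha)
      X0 <- U * X2
      cv0s <- sd(X0) / mean(X0); cv2s <- sd(X2) / mean(X2)
      v_u <- (cv0s^2 - cv2s^2) / (cv2s^2 + 1) / 4
      expect_lt(abs(v_u / beta_split_variance(alpha) - 1), 0.05,
                label = sprintf("alpha %g cv %g", alpha, cv2))
    }
  }
})

test_that("correlation tables are symmetric with unit diagonal and NA for constants", {
  p <- prc1_params(1)
  feats <- prc1dyn:::simulate_post_burnin(p, 100)
  ct <- correlation_table(feats)
  expect_equal(unclass(ct), t(unclass(ct)))
  expect_equal(unname(diag(ct)), rep(1, 10))
  expect_true(all(abs(ct) <= 1 + 1e-12))
  expect_equal(ct["T1+T2", "T1"],
               cor(feats$T1 + feats$T2, feats$T1))

  feats$b <- 0.5  # constant production rate
  ct2 <- correlation_table(feats)
  expect_true(all(is.na(ct2["b", ])))
  expect_true(all(is.na(ct2[, "ln(b)"])))
  expect_false(anyNA(ct2["X0", "X2"]))
  expect_error(correlation_table(feats[1:2, ]), "at least 3")
})

test_that("log-transformed rates correlate strongly with their raw scale", {
  # near-monotone transforms: ln(b) vs b is almost linear over its narrow
  # range; ln(a) vs a spans more curvature, so its correlation sits ~0.89
  ct <- simulated_correlation_table(prc1_params(1), 10000, seed = 6)
  expect_gte(ct["ln(a)", "a"], 0.85)
  expect_gte(ct["ln(b)", "b"], 0.95)
})

test_that("correlation tables survive the TSV round trip", {
  feats <- prc1dyn:::simulate_post_burnin(prc1_params(1), 200)
  ct <- correlation_table(feats)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_tsv(ct, tmp)
  back <- read_correlation_tsv(tmp)
  expect_equal(unclass(back), unclass(ct), tolerance = 1e-12)
})
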