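test_that("saturated fit reproduces the sample moments exactly with T = 0", {
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 400, seed = 5))
  sat <- saturated_model(colnames(obs))
  fit <- fit_ml(sat, obs, se = FALSE, standardized = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(fit$df, 0L)
  S <- cov(obs); mbar <- colMeans(obs)
  for (i in 1:8) {
    expect_equal(unname(fit$estimates[paste0("s_", colnames(obs)[i], "_",
                                             colnames(obs)[i])]),
                 unname(S[i, i]), tolerance = 1e-5)
    expect_equal(unname(fit$estimates[paste0("m_", colnames(obs)[i])]),
                 unname(mbar[i]), tolerance = 1e-5)
  }
})

test_that("baseline fit is closed-form and nests every fitted model", {
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 400, seed = 6))
  base <- baseline_fit(obs)
  expect_equal(base$df, 28L) # p(p+3)/2 - 2p at p = 8
  # diagonal sample covariance gives a zero baseline statistic
  d <- list(mean = c(0, 0), cov = diag(c(1, 2)), n = 50)
  expect_equal(baseline_fit(d)$chisq, 0, tolerance = 1e-12)
  fit <- fit_ml(build_riclpm(), obs, se = FALSE, standardized = FALSE)
  expect_gte(base$chisq, fit$chisq)
})

test_that("fit indices follow their definitions and flag df = 0", {
  expect_equal(fit_indices(12, 12, 100, 28)$cfi, 1)
  expect_equal(fit_indices(100, 28, 100, 28)$cfi, 0)
  idx <- fit_indices(44.646, 12, 300, 28)
  expect_equal(idx$cfi_raw, 1 - (44.646 - 12) / (300 - 28), tolerance = 1e-12)
  expect_equal(idx$tli_raw, ((300 / 28) - (44.646 / 12)) / ((300 / 28) - 1),
               tolerance = 1e-12)
  und <- fit_indices(0, 0, 100, 28)
  expect_true(is.na(und$cfi))
  expect_match(attr(und, "flag"), "df = 0")
  expect_error(fit_indices(10, 5, 0, 0), "baseline")
})

test_that("the minimizer sits below the generating values with a flat gradient", {
  tr <- quick_truth()
  model <- build_riclpm()
  obs <- panel_obs(generate_latent_panel(tr, 300, seed = 9))
  fit <- fit_ml(model, obs, se = FALSE, standardized = FALSE)
  expect_lt(fit$gradient_norm, 1e-4)
  # discrepancy at the optimum cannot exceed the discrepancy at the truth
  S <- cov(obs); mbar <- colMeans(obs); p <- 8
  f_at <- function(values) {
    mom <- implied_moments(model, values)
    si <- solve(unname(mom$sigma))
    d <- mbar - mom$mu
    as.numeric(determinant(unname(mom$sigma))$modulus -
                 determinant(S)$modulus) +
      sum(S * si) - p + drop(crossprod(d, si %*% d))
  }
  expect_lte(fit$fmin, f_at(riclpm_values(tr)) + 1e-8)
})

test_that("free parameters are recovered within reported uncertainty", {
  tr <- quick_truth()
  vals <- riclpm_values(tr)
  obs <- panel_obs(generate_latent_panel(tr, 4000, seed = 21))
  fit <- fit_ml(build_riclpm(), obs)
  expect_true(fit$converged)
  z <- (fit$estimates[names(vals)] - vals) / fit$se[names(vals)]
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(z)), 4)
})

test_that("standardization has the right fixed points and signs", {
  # AR(1) with stationary unit variances: standardized equals b
  b <- 0.5
  m <- ar1_model(3, b, 1 - b^2)
  # refit with the path free to obtain an estimate object
  vars <- paste0("y", 1:3)
  mf <- path_model(observed = vars)
  mf <- add_cov(mf, "y1", "y1", label = "v1")
  mf <- add_mean(mf, "y1", value = 0)
  for (t in 1:2) {
    mf <- add_path(mf, vars[t], vars[t + 1], label = paste0("b", t))
    mf <- add_cov(mf, vars[t + 1], vars[t + 1], label = paste0("q", t))
    mf <- add_mean(mf, vars[t + 1], value = 0)
  }
  mom <- implied_moments(ar1_model(3, b, 1 - b^2))
  fit <- fit_ml(mf, list(mean = mom$mu, cov = mom$sigma, n = 1000),
                se = FALSE, standardized = FALSE)
  std <- standardize(mf, fit)
  expect_equal(std$std, rep(b, 2), tolerance = 1e-5)
  expect_equal(std$estimate, rep(b, 2), tolerance = 1e-5)
  # sign of standardized equals sign of unstandardized
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 1500, seed = 33))
  f2 <- fit_ml(build_riclpm(), obs)
  s <- f2$standardized
  ok <- is.finite(s$std) & abs(s$estimate) > 1e-8
  expect_true(all(sign(s$std[ok]) == sign(s$estimate[ok])))
})

test_that("a constrained model never fits better than its nesting model", {
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 800, seed = 13))
  full <- fit_ml(build_riclpm(), obs, se = FALSE, standardized = FALSE)
  constrained <- fit_ml(build_riclpm(riclpm_options(cross_lags = FALSE)), obs,
                        se = FALSE, standardized = FALSE)
  expect_gte(constrained$chisq, full$chisq - 1e-6)
  expect_equal(constrained$df - full$df, 6L)
})

test_that("the chi-square multiplier switch rescales the statistic", {
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 500, seed = 17))
  f1 <- fit_ml(build_riclpm(), obs, se = FALSE, standardized = FALSE,
               multiplier = "n-1")
  f2 <- fit_ml(build_riclpm(), obs, se = FALSE, standardized = FALSE,
               multiplier = "n")
  expect_equal(f2$chisq / f1$chisq, 500 / 499, tolerance = 1e-6)
})
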