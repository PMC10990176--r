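test_that("rank correlation handles monotone, banded and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_ci(x, exp(x))$rho, 1)
  s <- spearman_ci(x, -x)
  expect_equal(s$rho, -1)
  expect_identical(spearman_ci(c(1, 2, 3, 4, 5), c(2, 1, 3, 5, 4))$magnitude,
                   "large")
  const <- spearman_ci(rep(1, 10), rnorm(10))
  expect_true(const$undefined)
  expect_error(spearman_ci(1:3, 3:1), "at least 4")
})

test_that("the magnitude bands split at 0.30 and 0.50 on absolute rho", {
  fake <- function(rho) {
    # construct vectors with approximately the wanted Spearman rho via
    # direct rank mixing, then read the band off the returned object
    set.seed(1)
    n <- 2000
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    spearman_ci(x, y)
  }
  expect_identical(fake(0.21)$magnitude, "small")
  expect_identical(fake(0.42)$magnitude, "medium")
  expect_identical(fake(0.75)$magnitude, "large")
})

test_that("Fisher-z interval approximates a bootstrap percentile interval", {
  set.seed(8)
  n <- 20
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  s <- spearman_ci(x, y)
  boots <- replicate(2000, {
    ix <- sample(n, replace = TRUE)
    suppressWarnings(stats::cor(x[ix], y[ix], method = "spearman"))
  })
  q <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  expect_lt(abs(s$lower - q[1]), 0.2)
  expect_lt(abs(s$upper - q[2]), 0.2)
})

test_that("signed-rank exact p-values equal brute-force enumeration", {
  # the printed example: differences +1, +2, +3, -4
  w <- wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, 2, 3, -4))
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, brute_signed_rank_p(c(1, 2, 3, -4)))
  # randomized cases with ties and zeros (Pratt handling)
  set.seed(9)
  for (i in 1:8) {
    d <- sample(-4:4, 9, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    out <- wilcoxon_signed_rank(rep(0, 9), d)
    expect_equal(out$p_value, brute_signed_rank_p(d), tolerance = 1e-12)
  }
  # tie-free case cross-checked against the base signed-rank distribution
  d <- c(1.1, -2.3, 3.7, 4.1, -5.9, 6.2, 7.8)
  out <- wilcoxon_signed_rank(rep(0, 7), d)
  V <- out$statistic
  p_base <- 2 * min(stats::psignrank(V, 7),
                    1 - stats::psignrank(V - 1, 7))
  expect_equal(out$p_value, min(1, p_base), tolerance = 1e-12)
  # degenerate: no nonzero differences
  expect_true(wilcoxon_signed_rank(1:4, 1:4)$undefined)
})

test_that("the large-sample approximation tracks the exact signed-rank p", {
  set.seed(10)
  for (i in 1:5) {
    d <- round(rnorm(25, 0.3, 1), 1)
    d[d == 0] <- 0.1
    exact <- wilcoxon_signed_rank(rep(0, 25), d, exact_limit = 25)
    approx <- wilcoxon_signed_rank(rep(0, 25), d, exact_limit = 10)
    expect_identical(approx$method, "normal approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("rank-sum exact p-values equal enumeration and are transform-invariant", {
  a <- c(1, 2, 3, 4, 5); b <- c(6, 7, 8, 9, 10)
  out <- mann_whitney(a, b)
  expect_equal(out$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(out$p_value, brute_rank_sum_p(a, b), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    g1 <- rnorm(5); g2 <- rnorm(4, 0.8)
    expect_equal(mann_whitney(g1, g2)$p_value, brute_rank_sum_p(g1, g2),
                 tolerance = 1e-12)
    # monotone transform leaves the test unchanged
    expect_equal(mann_whitney(exp(g1), exp(g2))$p_value,
                 mann_whitney(g1, g2)$p_value, tolerance = 1e-12)
  }
  near_id <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(near_id$p_value, 0.9)
})

test_that("median/IQR follow the interpolation rule with its equivariances", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(median_iqr(rep(4.2, 9))$iqr, 0)
  set.seed(12)
  x <- rnorm(40)
  s0 <- median_iqr(x); s1 <- median_iqr(x + 17)
  expect_equal(s1$median, s0$median + 17)
  expect_equal(s1$iqr, s0$iqr)
  expect_error(median_iqr(numeric()), "non-missing")
  # the rule switch changes rule-sensitive quantiles
  expect_false(isTRUE(all.equal(median_iqr(c(1, 2, 3, 4), type = 6)$iqr,
                                median_iqr(c(1, 2, 3, 4), type = 7)$iqr)))
})

test_that("panel descriptives reproduce the generator's configured centers", {
  d <- generate_cohort(quick_truth(), cohort_config(seed = 22))
  desc <- describe_panel(d$panel)
  tr <- quick_truth()
  for (t in 1:4) {
    med_tsk <- desc$by_wave$median[desc$by_wave$wave == t &
                                     desc$by_wave$variable == "tsk_total"]
    expect_lt(abs(med_tsk - tr$grand_means$tsk[t]), 3) # within half an IQR
    med_pa <- desc$by_wave$median[desc$by_wave$wave == t &
                                    desc$by_wave$variable == "pa_total"]
    expect_lt(abs(med_pa - tr$grand_means$pa[t]), 20)
  }
  expect_true(all(desc$severity$band %in%
                    c("subclinical", "mild", "moderate", "severe")))
  corr <- correlation_table(d$panel)
  expect_true(all(abs(corr$rho) <= 1))
  expect_true(all(corr$magnitude %in% c("small", "medium", "large")))
})
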