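test_that("the default builders reproduce the published df accounting", {
  m1 <- build_riclpm()
  expect_length(free_labels(m1), 32)
  expect_identical(model_df(m1), 12L)
  m2 <- build_ri_ar()
  expect_length(free_labels(m2), 24)
  expect_identical(model_df(m2), 20L)
})

test_that("builder switches move df by the expected amounts", {
  expect_length(free_labels(build_riclpm(riclpm_options(cross_lags = FALSE))),
                32 - 6)
  # freeing the dynamic residual covariances gives the textbook df = 9 variant
  expect_identical(
    model_df(build_riclpm(riclpm_options(dynamic_residual_covariances = TRUE))),
    9L)
  # dropping the concurrent covariances raises df by the number of waves
  expect_identical(model_df(build_ri_ar(concurrent_covariances = FALSE)),
                   24L)
  # boundary: 2 waves may over-parameterize, flagged not silent
  expect_warning(df2 <- model_df(build_riclpm(riclpm_options(n_waves = 2))),
                 "over-parameterized")
  expect_lt(as.integer(df2), 0)
})

test_that("df arithmetic equals brute-force label enumeration", {
  for (m in list(build_riclpm(), build_ri_ar(),
                 build_riclpm(riclpm_options(cross_lags = FALSE)))) {
    p <- length(m$observed)
    labs <- unique(stats::na.omit(c(m$paths$label, m$covs$label,
                                    m$means$label)))
    expect_identical(as.integer(model_df(m)),
                     as.integer(p * (p + 3) / 2 - length(labs)))
  }
})

test_that("fixing any single free parameter raises df by exactly one", {
  m <- build_riclpm()
  base_df <- model_df(m)
  fix_label <- function(model, lab) {
    for (tab in c("paths", "covs", "means")) {
      hit <- !is.na(model[[tab]]$label) & model[[tab]]$label == lab
      model[[tab]]$label[hit] <- NA_character_
    }
    model
  }
  for (lab in c("a_tsk_t1", "ri_cov", "mu_pa_3", "rv_pa_t2")) {
    expect_identical(model_df(fix_label(m, lab)), base_df + 1L)
  }
})

test_that("effect sizes are labelled by absolute magnitude", {
  expect_identical(effect_size_label(0.53), "large")
  expect_identical(effect_size_label(0.15), "small")
  expect_identical(effect_size_label(-0.45), "moderate")
  expect_identical(effect_size_label(c(0.29, 0.30, 0.499, 0.50)),
                   c("small", "moderate", "moderate", "large"))
  expect_error(effect_size_label(NaN), "finite")
})

test_that("truth parameters cover exactly the RI-CLPM free labels", {
  vals <- riclpm_values(default_truth_params())
  expect_setequal(names(vals), free_labels(build_riclpm()))
})

test_that("trait-model standardized loadings differ across waves with unequal residuals", {
  m <- build_ri_ar()
  vals <- c(
    stats::setNames(rep(27, 4), paste0("mu_tsk_", 1:4)),
    stats::setNames(rep(100, 4), paste0("mu_pa_", 1:4)),
    ri_var_tsk = 15,
    stats::setNames(c(20, 6, 7, 19), paste0("ev_tsk_", 1:4)),
    stats::setNames(rep(0, 4), paste0("cc_w", 1:4)),
    pa_var_1 = 900,
    stats::setNames(rep(0.5, 3), paste0("a_pa_t", 1:3)),
    stats::setNames(rep(600, 3), paste0("rv_pa_t", 1:3))
  )
  fake_fit <- structure(list(estimates = vals, acov = NULL), class = "sem_fit")
  std <- standardize(m, fake_fit)
  loadings <- std$std[std$from == "ri_tsk"]
  expect_length(unique(round(loadings, 6)), 4)
  # larger residual variance means a smaller standardized loading
  expect_lt(loadings[1], loadings[2])
})

test_that("panel fits are invariant to patient row permutation", {
  tr <- quick_truth()
  cohort <- generate_cohort(tr, cohort_config(seed = 5), missingness = FALSE)
  wide <- panel_wide(cohort$panel)
  f1 <- fit_panel(build_riclpm(), wide, se = FALSE, standardized = TRUE)
  set.seed(2)
  f2 <- fit_panel(build_riclpm(), wide[sample(nrow(wide)), ], se = FALSE,
                  standardized = TRUE)
  expect_equal(f1$table$std, f2$table$std, tolerance = 1e-6)
})

test_that("report rows follow the published table layout", {
  tr <- quick_truth()
  obs <- panel_obs(generate_latent_panel(tr, 600, seed = 8))
  f <- fit_panel(build_riclpm(), obs, se = TRUE, standardized = TRUE)
  # dependent blocks: TSK waves 2..4 first, then PA waves 2..4, two rows each
  expect_identical(f$table$block,
                   rep(c(paste0("tsk_w", 2:4), paste0("pa_w", 2:4)), each = 2))
  expect_true(all(c("std", "lower", "upper", "p_value", "magnitude") %in%
                    names(f$table)))
  f2 <- fit_panel(build_ri_ar(), obs, se = TRUE, standardized = TRUE)
  expect_identical(f2$table$block, c(rep("ri_tsk", 4), rep("pa_ar", 3)))
})

test_that("long and wide panel representations agree", {
  cohort <- generate_cohort(config = cohort_config(seed = 3))
  wide <- panel_wide(cohort$panel)
  expect_identical(dim(wide), c(116L, 8L))
  one <- cohort$panel[cohort$panel$patient_id == 7, ]
  expect_equal(unname(wide[7, "tsk_w2"]), unname(one$tsk_total[one$wave == 2]))
  expect_equal(unname(wide[7, "pa_w4"]), unname(one$pa_total[one$wave == 4]))
  # missing questionnaire cells surface as NA in the wide table
  expect_identical(unname(is.na(wide[7, paste0("tsk_w", 1:4)])),
                   one$tsk_missing)
})
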