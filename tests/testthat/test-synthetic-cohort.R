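test_that("generation is bit-identical under a fixed seed", {
  tr <- quick_truth()
  cfg <- cohort_config(seed = 77)
  d1 <- generate_cohort(tr, cfg)
  d2 <- generate_cohort(tr, cfg)
  expect_identical(d1$panel, d2$panel)
  expect_identical(d1$items, d2$items)
  p3 <- generate_latent_panel(tr, 50, seed = 4)
  p4 <- generate_latent_panel(tr, 50, seed = 4)
  expect_identical(p3, p4)
})

test_that("zero random-intercept variance degenerates to pure within dynamics", {
  tr <- quick_truth()
  tr0 <- truth_params(
    grand_means = tr$grand_means, ri_variances = c(0, 0), ri_covariance = 0,
    wave1_within_cov = tr$wave1_within_cov, lagged_coefs = tr$lagged_coefs,
    residual_variances = tr$residual_variances
  )
  pan <- generate_latent_panel(tr0, 100, seed = 2)
  expect_true(all(pan$b_tsk == 0) && all(pan$b_pa == 0))
  expect_equal(pan$tsk_w2, tr0$grand_means$tsk[2] + pan$w_tsk_w2)
})

test_that("invalid truth blocks are rejected with the offending block named", {
  tr <- quick_truth()
  expect_error(
    truth_params(grand_means = tr$grand_means, ri_variances = c(15, 640),
                 wave1_within_cov = matrix(c(1, 2, 2, 1), 2),
                 lagged_coefs = tr$lagged_coefs,
                 residual_variances = tr$residual_variances),
    "wave1_within_cov")
  expect_error(
    truth_params(grand_means = tr$grand_means, ri_variances = c(15, 640),
                 wave1_within_cov = tr$wave1_within_cov,
                 lagged_coefs = tr$lagged_coefs,
                 residual_variances = list(c(1, 1), c(1, 1), c(-1, 1))),
    "residual_variances\\[\\[3\\]\\]")
})

test_that("item disaggregation conserves totals at the extremes and in between", {
  expect_identical(disaggregate_tsk_items(13, seed = 1), rep(1L, 13))
  expect_identical(disaggregate_tsk_items(52, seed = 1), rep(4L, 13))
  set.seed(99)
  for (tot in sample(13:52, 15)) {
    items <- disaggregate_tsk_items(tot)
    expect_identical(sum(items), as.integer(tot))
    expect_true(all(items >= 1 & items <= 4))
  }
  expect_error(disaggregate_tsk_items(12), "13..52")
  expect_error(disaggregate_tsk_items(53), "13..52")
})

test_that("generated MET days hit their category targets exactly", {
  d0 <- generate_met_day(c(0, 0, 0), seed = 3)
  s0 <- summarize_day(d0)
  expect_equal(c(s0$minutes_light, s0$minutes_moderate, s0$minutes_heavy),
               c(0, 0, 0))
  d1 <- generate_met_day(c(54, 24, 0), seed = 3)
  s1 <- summarize_day(d1)
  expect_equal(c(s1$minutes_light, s1$minutes_moderate, s1$minutes_heavy),
               c(54, 24, 0))
  # brute-force epoch count at 1-minute resolution
  d2 <- generate_met_day(c(60, 30, 2), seed = 7)
  expect_identical(sum(d2$met > cutpoints()$sedentary_max), 92L)
  expect_error(generate_met_day(c(1400, 100, 0)), "exceed")
})

test_that("round-trip conservation holds for random feasible targets", {
  set.seed(123)
  for (i in 1:10) {
    tgt <- c(sample(0:300, 1), sample(0:120, 1), sample(0:20, 1))
    s <- summarize_day(generate_met_day(tgt))
    expect_equal(c(s$minutes_light, s$minutes_moderate, s$minutes_heavy),
                 tgt)
  }
})

test_that("the exclusion flow reproduces the printed cohort and edge cases", {
  flow <- apply_cohort_flow(cohort_config())
  expect_identical(flow$remaining, c(188L, 186L, 149L, 116L))
  flow2 <- apply_cohort_flow(cohort_config(
    n_assessed = 10, n_died = 0, n_questionnaire_completers = 10,
    n_no_accelerometer = 0, tsk_wave_missing_rates = rep(0, 4)))
  expect_identical(flow2$remaining[4], 10L)
  expect_warning(
    flow3 <- apply_cohort_flow(cohort_config(
      n_assessed = 5, n_died = 0, n_questionnaire_completers = 5,
      n_no_accelerometer = 5, tsk_wave_missing_rates = rep(0, 4))),
    "empty")
  expect_identical(flow3$remaining[4], 0L)
  expect_error(cohort_config(n_assessed = 100, n_questionnaire_completers = 120),
               "n_questionnaire_completers")
})

test_that("missingness is imposed at the configured wave rates", {
  tr <- quick_truth()
  # zero rates leave the dataset untouched
  cfg0 <- cohort_config(seed = 8, tsk_wave_missing_rates = rep(0, 4),
                        epoch_missing_rate = 0)
  d0 <- generate_cohort(tr, cfg0)
  expect_false(any(d0$panel$tsk_missing))
  expect_false(anyNA(d0$panel$tsk_total))
  # rate 1 at wave 4 deletes every wave-4 questionnaire
  cfg1 <- cohort_config(seed = 8, tsk_wave_missing_rates = c(0, 0, 0, 1))
  d1 <- generate_cohort(tr, cfg1)
  expect_true(all(is.na(d1$panel$tsk_total[d1$panel$wave == 4])))
  expect_false(anyNA(d1$panel$tsk_total[d1$panel$wave != 4]))
  # realized rates approach targets in a large cohort
  cfgN <- cohort_config(n_assessed = 10000, n_died = 0,
                        n_questionnaire_completers = 10000,
                        n_no_accelerometer = 0, seed = 15)
  dN <- generate_cohort(tr, cfgN)
  for (t in 1:4) {
    realized <- mean(dN$panel$tsk_missing[dN$panel$wave == t])
    expect_lt(abs(realized - cfgN$tsk_wave_missing_rates[t]), 0.02)
  }
  # masks are stored, not silently dropped
  expect_identical(is.na(dN$panel$tsk_total), dN$panel$tsk_missing)
  expect_identical(dN$items$missing[match(
    paste(dN$panel$patient_id, dN$panel$wave),
    paste(dN$items$patient_id, dN$items$wave))], dN$panel$tsk_missing)
})

test_that("stored items re-score to the panel totals", {
  d <- generate_cohort(quick_truth(), cohort_config(seed = 31))
  obs_rows <- !d$items$missing
  totals <- score_tsk(as.matrix(d$items[obs_rows, paste0("item_", 1:13)]))
  key <- paste(d$items$patient_id, d$items$wave)[obs_rows]
  panel_tot <- d$panel$tsk_total[match(key, paste(d$panel$patient_id,
                                                  d$panel$wave))]
  expect_equal(as.numeric(totals), panel_tot)
})

test_that("epoch streams reproduce wave-week activity through the aggregator", {
  tr <- quick_truth()
  cfg <- cohort_config(n_assessed = 3, n_died = 0,
                       n_questionnaire_completers = 3, n_no_accelerometer = 0,
                       wear_days = 21, seed = 44,
                       tsk_wave_missing_rates = rep(0, 4),
                       epoch_missing_rate = 0)
  d <- generate_cohort(tr, cfg, epochs = TRUE)
  expect_identical(nrow(d$epochs), 3L * 21L * 1440L)
  ep1 <- d$epochs[d$epochs$patient_id == 1, ]
  daily <- summarize_days(ep1)
  weekly <- weekly_average(daily, weeks = 1:3)
  wave <- extract_wave_pa(weekly, wave_weeks = c(1, 3, 6, 12))
  truth_w1 <- d$panel[d$panel$patient_id == 1 & d$panel$wave == 1, ]
  # wave 1 covers week 1 exactly; targets recovered to epoch resolution
  expect_equal(wave$pa_light[1], truth_w1$pa_light, tolerance = 0.5)
  expect_equal(wave$pa_total[1], truth_w1$pa_total, tolerance = 1.5)
  # waves beyond the wear window are missing, not zero
  expect_true(is.na(wave$pa_total[3]))
})

test_that("cohort files are written as plain text", {
  d <- generate_cohort(quick_truth(), cohort_config(seed = 12))
  dir <- withr::local_tempdir()
  files <- write_cohort(d, dir)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(file.path(dir, "panel.csv"))
  expect_identical(nrow(back), nrow(d$panel))
  flow <- jsonlite::fromJSON(file.path(dir, "flow.json"))
  expect_identical(flow$remaining[4], 116L)
})
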