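# Seeded synthetic cohorts with the latent trait/state dependence structure
# the panel analysis assumes: every downstream stage is testable without any
# patient data.

#' Generating ("truth") parameters of the latent panel process
#'
#' Observed scores at each wave are grand mean + stable between-person
#' component (random intercept) + fluctuating within-person component. Within
#' components evolve wave-to-wave through a 2x2 lagged-coefficient matrix
#' (diagonal: autoregressive; off-diagonal: cross-lagged) plus a residual
#' disturbance. Process order is (kinesiophobia, activity) throughout.
#'
#' @param grand_means list with numeric vectors `tsk` and `pa`, one mean per
#'   wave (TSK points; activity minutes/day).
#' @param ri_variances length-2 nonnegative: random-intercept variances.
#' @param ri_covariance random-intercept covariance.
#' @param wave1_within_cov 2x2 symmetric positive-definite within covariance
#'   at wave 1.
#' @param lagged_coefs list (one 2x2 matrix per transition); rows index the
#'   outcome at t+1, columns the predictor at t.
#' @param residual_variances list (one length-2 positive vector per
#'   transition).
#' @param residual_covariances numeric, one per transition (default 0).
#' @return A validated list of class `truth_params`.
#' @export
truth_params <- function(grand_means, ri_variances, ri_covariance = 0,
                         wave1_within_cov, lagged_coefs, residual_variances,
                         residual_covariances = NULL) {
  stopifnot(is.list(grand_means), all(c("tsk", "pa") %in% names(grand_means)))
  n_waves <- length(grand_means$tsk)
  if (length(grand_means$pa) != n_waves) {
    stop("grand_means$tsk and grand_means$pa must have equal length")
  }
  if (n_waves < 2) stop("need at least 2 waves")
  nt <- n_waves - 1
  residual_covariances <- residual_covariances %||% rep(0, nt)
  if (length(ri_variances) != 2 || any(ri_variances < 0)) {
    stop("ri_variances must be 2 nonnegative reals")
  }
  ri <- matrix(c(ri_variances[1], ri_covariance,
                 ri_covariance, ri_variances[2]), 2, 2)
  check_spd(ri, "random-intercept covariance block", strict = FALSE)
  check_spd(wave1_within_cov, "wave1_within_cov", strict = TRUE)
  if (length(lagged_coefs) != nt || length(residual_variances) != nt ||
      length(residual_covariances) != nt) {
    stop(sprintf("need %d transitions of lagged_coefs / residual_variances / residual_covariances",
                 nt))
  }
  for (t in seq_len(nt)) {
    if (!is.matrix(lagged_coefs[[t]]) || any(dim(lagged_coefs[[t]]) != 2)) {
      stop(sprintf("lagged_coefs[[%d]] must be a 2x2 matrix", t))
    }
    rv <- residual_variances[[t]]
    if (length(rv) != 2 || any(rv <= 0)) {
      stop(sprintf("residual_variances[[%d]] must be 2 positive reals", t))
    }
    R <- matrix(c(rv[1], residual_covariances[t],
                  residual_covariances[t], rv[2]), 2, 2)
    check_spd(R, sprintf("residual covariance block (transition %d)", t),
              strict = TRUE)
  }
  structure(
    list(n_waves = n_waves, grand_means = grand_means,
         ri_variances = as.numeric(ri_variances),
         ri_covariance = as.numeric(ri_covariance),
         wave1_within_cov = wave1_within_cov,
         lagged_coefs = lagged_coefs,
         residual_variances = lapply(residual_variances, as.numeric),
         residual_covariances = as.numeric(residual_covariances)),
    class = "truth_params"
  )
}

#' Default truth parameters matching the study's printed summaries
#'
#' Grand means follow the published wave medians (TSK 27.4 to 25.0 points;
#' total activity 82.1, 127.5, 127.0, 123.9 minutes/day). Spreads convert the
#' printed IQRs to normal SDs (IQR/1.349) and split total variance roughly
#' half-and-half between the random intercept and the wave-1 within component.
#' Lagged coefficients are the published standardized path estimates converted
#' to the raw scale under the wave-1 within SDs; residual variances are chosen
#' so the within variances stay approximately stationary across waves. All
#' defaults are plain numbers; pass your own [truth_params()] to override.
#'
#' @param cross_lags set the four cross-lagged entries; `FALSE` zeroes them
#'   (the "no cross-over effect" generating condition).
#' @return A [truth_params()] object.
#' @export
default_truth_params <- function(cross_lags = TRUE) {
  sd_tsk <- sqrt(14)   # within-SD; total var 29 ~ (7.28 / 1.349)^2
  sd_pa <- sqrt(960)   # within-SD; total var 1600 ~ (54 / 1.349)^2
  # standardized (ar_tsk, cl_tsk<-pa, cl_pa<-tsk, ar_pa) per transition
  std <- list(c(0.53, 0.12, 0.09, 0.52),
              c(0.61, 0.15, 0.09, 0.67),
              c(0.53, -0.04, -0.01, 0.65))
  lagged <- list(); resid <- list()
  for (t in 1:3) {
    b <- std[[t]]
    if (!cross_lags) b[2:3] <- 0
    lagged[[t]] <- matrix(c(b[1], b[2] * sd_tsk / sd_pa,
                            b[3] * sd_pa / sd_tsk, b[4]),
                          2, 2, byrow = TRUE)
    resid[[t]] <- c(sd_tsk^2 * max(1 - b[1]^2 - b[2]^2, 0.2),
                    sd_pa^2 * max(1 - b[4]^2 - b[3]^2, 0.2))
  }
  truth_params(
    grand_means = list(tsk = c(27.4, 26.6, 25.8, 25.0),
                       pa = c(82.09, 127.50, 127.00, 123.85)),
    ri_variances = c(15, 640),
    ri_covariance = 0,
    wave1_within_cov = diag(c(sd_tsk^2, sd_pa^2)),
    lagged_coefs = lagged,
    residual_variances = resid
  )
}

#' Cohort design configuration
#'
#' Encodes the enrolment flow, measurement design and missingness rates the
#' generator emulates: 188 assessed, 2 deaths, 149 questionnaire completers,
#' 33 accelerometer non-wearers (analysis n = 116); 4 waves at weeks 1, 3, 6,
#' 12 post-discharge; 90 wear days at 1-minute epochs; wave-level
#' questionnaire missingness of 22.8/24.8/28.2/36.2% and 14.4% epoch-level
#' accelerometer missingness.
#'
#' @param n_assessed,n_died,n_questionnaire_completers,n_no_accelerometer
#'   cohort-flow counts.
#' @param n_waves,wave_weeks measurement occasions and their week indices.
#' @param wear_days accelerometer wear period in days (a 14-day "desk" value
#'   keeps test runs light).
#' @param epoch_minutes epoch length in minutes.
#' @param tsk_wave_missing_rates per-wave questionnaire missingness
#'   proportions.
#' @param epoch_missing_rate epoch-level accelerometer missingness proportion.
#' @param seed default seed for [generate_cohort()].
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_assessed = 188, n_died = 2,
                          n_questionnaire_completers = 149,
                          n_no_accelerometer = 33,
                          n_waves = 4, wave_weeks = c(1, 3, 6, 12),
                          wear_days = 90, epoch_minutes = 1,
                          tsk_wave_missing_rates = c(0.228, 0.248, 0.282, 0.362),
                          epoch_missing_rate = 0.144,
                          seed = 1234L) {
  n_assessed <- assert_count(n_assessed, "n_assessed", 1)
  n_died <- assert_count(n_died, "n_died", 0)
  n_questionnaire_completers <-
    assert_count(n_questionnaire_completers, "n_questionnaire_completers", 0)
  n_no_accelerometer <- assert_count(n_no_accelerometer, "n_no_accelerometer", 0)
  if (n_assessed < n_questionnaire_completers) {
    stop("n_assessed must be at least n_questionnaire_completers")
  }
  if (n_assessed - n_died < n_questionnaire_completers) {
    stop("completers cannot exceed assessed minus deaths")
  }
  if (n_questionnaire_completers - n_no_accelerometer < 0) {
    stop("accelerometer non-wearers cannot exceed questionnaire completers")
  }
  n_waves <- assert_count(n_waves, "n_waves", 2)
  stopifnot(length(wave_weeks) == n_waves, all(diff(wave_weeks) > 0))
  assert_count(wear_days, "wear_days", 1)
  assert_number(epoch_minutes, "epoch_minutes", lower = 1 / 60, upper = 60)
  assert_proportion(tsk_wave_missing_rates, "tsk_wave_missing_rates")
  stopifnot(length(tsk_wave_missing_rates) == n_waves)
  assert_proportion(epoch_missing_rate, "epoch_missing_rate")
  structure(
    list(n_assessed = n_assessed, n_died = n_died,
         n_questionnaire_completers = n_questionnaire_completers,
         n_no_accelerometer = n_no_accelerometer,
         n_waves = n_waves, wave_weeks = wave_weeks,
         wear_days = as.integer(wear_days), epoch_minutes = epoch_minutes,
         tsk_wave_missing_rates = tsk_wave_missing_rates,
         epoch_missing_rate = epoch_missing_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Apply the cohort exclusion flow
#'
#' @param config a [cohort_config()].
#' @return A [tibble::tibble()] ledger with one row per stage (`stage`,
#'   `removed`, `remaining`), ending at the analysis-sample count
#'   (completers minus accelerometer non-wearers). An empty final sample is
#'   flagged via the `"empty_analysis_set"` attribute.
#' @export
apply_cohort_flow <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  other <- config$n_assessed - config$n_died - config$n_questionnaire_completers
  final <- config$n_questionnaire_completers - config$n_no_accelerometer
  ledger <- tibble::tibble(
    stage = c("assessed for eligibility", "died after inclusion",
              "did not complete questionnaires", "did not wear accelerometer"),
    removed = c(0L, config$n_died, other, config$n_no_accelerometer),
    remaining = c(config$n_assessed,
                  config$n_assessed - config$n_died,
                  config$n_questionnaire_completers,
                  final)
  )
  if (final == 0) {
    warning("cohort flow leaves an empty analysis set")
    attr(ledger, "empty_analysis_set") <- TRUE
  }
  ledger
}

#' Simulate the latent panel process
#'
#' Draws `n` patients from the trait/state decomposition: between components
#' from the random-intercept covariance, wave-1 within components from the
#' wave-1 covariance, later within components through the lagged-coefficient
#' recursion with multivariate-normal residuals. Observed value = grand mean
#' + between + within. This simulator shares no code with
#' [implied_moments()], so the two serve as mutual oracles.
#'
#' @param truth a [truth_params()].
#' @param n number of patients.
#' @param seed integer seed (`NULL` to use the ambient RNG stream).
#' @return A [tibble::tibble()] with per-patient between components (`b_tsk`,
#'   `b_pa`), within components (`w_tsk_w*`, `w_pa_w*`) and observed values
#'   (`tsk_w*`, `pa_w*`).
#' @export
generate_latent_panel <- function(truth, n, seed = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  n <- assert_count(n, "n", lower = 1)
  nw <- truth$n_waves
  with_seed_opt(seed, {
    ri <- matrix(c(truth$ri_variances[1], truth$ri_covariance,
                   truth$ri_covariance, truth$ri_variances[2]), 2, 2)
    B <- rmvn(n, c(0, 0), ri)
    W <- vector("list", nw)
    W[[1]] <- rmvn(n, c(0, 0), truth$wave1_within_cov)
    for (t in seq_len(nw - 1)) {
      rv <- truth$residual_variances[[t]]
      R <- matrix(c(rv[1], truth$residual_covariances[t],
                    truth$residual_covariances[t], rv[2]), 2, 2)
      W[[t + 1]] <- W[[t]] %*% t(truth$lagged_coefs[[t]]) + rmvn(n, c(0, 0), R)
    }
    out <- tibble::tibble(patient_id = seq_len(n),
                          b_tsk = B[, 1], b_pa = B[, 2])
    for (t in seq_len(nw)) {
      out[[paste0("w_tsk_w", t)]] <- W[[t]][, 1]
      out[[paste0("w_pa_w", t)]] <- W[[t]][, 2]
    }
    for (t in seq_len(nw)) {
      out[[paste0("tsk_w", t)]] <-
        truth$grand_means$tsk[t] + B[, 1] + W[[t]][, 1]
      out[[paste0("pa_w", t)]] <-
        truth$grand_means$pa[t] + B[, 2] + W[[t]][, 2]
    }
    out
  })
}

#' Disaggregate a questionnaire total into 13 item scores
#'
#' Allocates the excess over the floor score (13 items scored 1) uniformly at
#' random across items, each capped at 4, so the items always sum exactly to
#' the total.
#'
#' @param total integer total(s) in 13..52.
#' @param seed integer seed (`NULL` for ambient stream).
#' @return For a single total, an integer vector of 13 item scores in 1..4;
#'   for a vector of totals, a matrix with one row per total.
#' @export
disaggregate_tsk_items <- function(total, seed = NULL) {
  if (any(!is.finite(total)) || any(total != round(total)) ||
      any(total < 13) || any(total > 52)) {
    stop("`total` must be integer(s) in 13..52")
  }
  with_seed_opt(seed, {
    one <- function(tot) {
      excess <- tot - 13L
      pool <- rep(1:13, times = 3) # each item can absorb up to 3 extra points
      extra <- tabulate(sample(pool, excess), nbins = 13)
      as.integer(1L + extra)
    }
    if (length(total) == 1L) one(total) else
      t(vapply(total, one, integer(13)))
  })
}

#' Generate one day of accelerometer epochs hitting given activity targets
#'
#' Produces an epoch stream covering a full day in which exactly
#' `round(target/epoch_minutes)` epochs fall in each activity category;
#' remaining epochs are sedentary (MET at or below the sedentary cutpoint).
#' Active epochs carry MET values drawn uniformly inside their category's
#' interval, and active positions are scattered uniformly over the day, so
#' [summarize_day()] recovers the targets exactly at epoch resolution.
#'
#' @param target_minutes length-3 numeric `(light, moderate, heavy)` minutes.
#' @param date calendar date of the epochs.
#' @param cuts a [cutpoints()].
#' @param epoch_minutes epoch length in minutes.
#' @param seed integer seed (`NULL` for ambient stream).
#' @return A [tibble::tibble()] with `timestamp` (POSIXct, UTC) and `met`.
#' @export
generate_met_day <- function(target_minutes, date = as.Date("2020-01-01"),
                             cuts = cutpoints(), epoch_minutes = 1,
                             seed = NULL) {
  stopifnot(length(target_minutes) == 3, all(is.finite(target_minutes)),
            all(target_minutes >= 0))
  n_epochs <- floor(24 * 60 / epoch_minutes)
  counts <- round(target_minutes / epoch_minutes)
  if (sum(counts) > n_epochs) {
    stop(sprintf("activity targets (%.0f min) exceed the day length",
                 sum(target_minutes)))
  }
  with_seed_opt(seed, {
    met <- stats::runif(n_epochs, min(0.9, cuts$sedentary_max), cuts$sedentary_max)
    n_active <- sum(counts)
    if (n_active > 0) {
      pos <- sample(n_epochs, n_active)
      cat_draw <- c(
        stats::runif(counts[1], cuts$sedentary_max, cuts$light_max),
        stats::runif(counts[2], cuts$light_max, cuts$moderate_max),
        stats::runif(counts[3], cuts$moderate_max, 2 * cuts$moderate_max)
      )
      met[pos] <- cat_draw
    }
    tibble::tibble(
      timestamp = as.POSIXct(as.Date(date), tz = "UTC") +
        (seq_len(n_epochs) - 1) * epoch_minutes * 60,
      met = met
    )
  })
}

#' Impose MCAR missingness on a cohort dataset
#'
#' Deletes each wave-level questionnaire record independently with its wave's
#' rate (total and items set to `NA`, the mask retained in `tsk_missing`),
#' and flags each accelerometer epoch independently with the epoch rate
#' (column `missing`; epochs are never silently dropped).
#'
#' @param dataset a `cohort_dataset` from [generate_cohort()].
#' @param config a [cohort_config()] carrying the rates.
#' @param seed integer seed (`NULL` for ambient stream).
#' @return The dataset with missingness applied and masks stored.
#' @export
impose_missingness <- function(dataset, config = dataset$config, seed = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  assert_proportion(config$tsk_wave_missing_rates, "tsk_wave_missing_rates")
  assert_proportion(config$epoch_missing_rate, "epoch_missing_rate")
  with_seed_opt(seed, {
    panel <- dataset$panel
    for (t in seq_len(config$n_waves)) {
      sel <- which(panel$wave == t)
      hit <- stats::runif(length(sel)) < config$tsk_wave_missing_rates[t]
      panel$tsk_missing[sel] <- hit
      panel$tsk_total[sel[hit]] <- NA_real_
    }
    items <- dataset$items
    if (!is.null(items)) {
      key <- paste(items$patient_id, items$wave)
      miss_key <- paste(panel$patient_id, panel$wave)[panel$tsk_missing]
      hit <- key %in% miss_key
      items[hit, paste0("item_", 1:13)] <- NA_integer_
      items$missing <- hit
    }
    epochs <- dataset$epochs
    if (!is.null(epochs) && nrow(epochs) > 0) {
      epochs$missing <- stats::runif(nrow(epochs)) < config$epoch_missing_rate
    }
    dataset$panel <- panel
    dataset$items <- items
    dataset$epochs <- epochs
    dataset
  })
}

# Wave-specific activity-category shares, from the published category medians.
pa_category_shares <- function() {
  med <- rbind(c(54.14, 24.34, 0.43),
               c(82.86, 39.21, 0.57),
               c(84.04, 35.50, 0.83),
               c(81.34, 40.15, 1.15))
  med / rowSums(med)
}

#' Generate a complete synthetic cohort dataset
#'
#' Runs the full generative pipeline: exclusion flow, latent panel draws,
#' questionnaire totals (rounded and clamped to 13..52) disaggregated into
#' item scores, activity totals (floored at 0) split into light/moderate/heavy
#' minutes by Dirichlet-perturbed wave-specific shares, optional epoch
#' streams, then MCAR missingness.
#'
#' @param truth a [truth_params()] (defaults to [default_truth_params()]).
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param epochs generate epoch-level accelerometer streams? Off by default
#'   (a 90-day 1-minute stream for a full cohort is ~17 million epochs);
#'   weekly category targets are linearly interpolated between waves, held
#'   constant within each 7-day window.
#' @param missingness apply [impose_missingness()]?
#' @return A list of class `cohort_dataset`: `flow` (ledger), `panel` (long
#'   wave panel with masks), `items` (13 item scores per patient-wave),
#'   `epochs` (or `NULL`), plus the `config` and `truth` used.
#' @export
generate_cohort <- function(truth = default_truth_params(),
                            config = cohort_config(),
                            seed = config$seed,
                            epochs = FALSE, missingness = TRUE) {
  flow <- apply_cohort_flow(config)
  n <- flow$remaining[nrow(flow)]
  if (n < 1) stop("cohort flow leaves no patients to generate")
  with_seed_opt(seed, {
    latent <- generate_latent_panel(truth, n)
    nw <- config$n_waves
    panel <- tibble::tibble(
      patient_id = rep(seq_len(n), each = nw),
      wave = rep(seq_len(nw), times = n),
      week = rep(config$wave_weeks, times = n),
      tsk_total = NA_real_, pa_light = NA_real_, pa_moderate = NA_real_,
      pa_heavy = NA_real_, pa_total = NA_real_,
      tsk_missing = FALSE, pa_missing = FALSE
    )
    shares <- pa_category_shares()
    if (nrow(shares) != nw) shares <- shares[rep(1, nw), , drop = FALSE]
    item_rows <- vector("list", nw)
    for (t in seq_len(nw)) {
      sel <- which(panel$wave == t)
      tsk <- pmin(pmax(round(latent[[paste0("tsk_w", t)]]), 13), 52)
      pa <- pmax(latent[[paste0("pa_w", t)]], 0)
      # Dirichlet perturbation of the wave's category shares
      g <- matrix(stats::rgamma(3 * n, shape = rep(shares[t, ] * 60, each = n)),
                  n, 3)
      prop <- g / rowSums(g)
      panel$tsk_total[sel] <- tsk
      panel$pa_light[sel] <- pa * prop[, 1]
      panel$pa_moderate[sel] <- pa * prop[, 2]
      panel$pa_heavy[sel] <- pa * prop[, 3]
      panel$pa_total[sel] <- pa
      its <- disaggregate_tsk_items(tsk)
      if (is.null(dim(its))) its <- matrix(its, nrow = 1)
      item_rows[[t]] <- cbind(patient_id = seq_len(n), wave = t,
                              as.data.frame(its))
    }
    items <- do.call(rbind, item_rows)
    names(items)[3:15] <- paste0("item_", 1:13)
    items <- items[order(items$patient_id, items$wave), ]
    items$missing <- FALSE
    items <- tibble::as_tibble(items)

    epoch_tab <- NULL
    if (isTRUE(epochs)) {
      epoch_tab <- generate_epoch_streams(panel, config)
    }
    dataset <- structure(
      list(flow = flow, panel = panel, items = items, epochs = epoch_tab,
           config = config, truth = truth),
      class = "cohort_dataset"
    )
    if (isTRUE(missingness)) dataset <- impose_missingness(dataset, config)
    dataset
  })
}

# Daily category targets: wave values held constant over each wave's week,
# linearly interpolated between wave weeks, constant after the last wave.
weekly_targets <- function(panel_patient, wave_weeks, n_weeks) {
  interp <- function(values) {
    stats::approx(x = wave_weeks, y = values, xout = seq_len(n_weeks),
                  rule = 2)$y
  }
  cbind(light = interp(panel_patient$pa_light),
        moderate = interp(panel_patient$pa_moderate),
        heavy = interp(panel_patient$pa_heavy))
}

generate_epoch_streams <- function(panel, config) {
  n_weeks <- ceiling(config$wear_days / 7)
  start <- as.Date("2020-01-01")
  out <- vector("list", length(unique(panel$patient_id)))
  for (id in unique(panel$patient_id)) {
    pp <- panel[panel$patient_id == id, ]
    tg <- weekly_targets(pp, config$wave_weeks, n_weeks)
    days <- vector("list", config$wear_days)
    for (d in seq_len(config$wear_days)) {
      wk <- ceiling(d / 7)
      day <- generate_met_day(tg[wk, ], date = start + (d - 1),
                              epoch_minutes = config$epoch_minutes)
      day$patient_id <- id
      day$day <- d
      days[[d]] <- day
    }
    out[[id]] <- do.call(rbind, days)
  }
  ep <- do.call(rbind, out)
  ep$missing <- FALSE
  ep[, c("patient_id", "day", "timestamp", "met", "missing")]
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n <- length(unique(x$panel$patient_id))
  cat(sprintf("<cohort_dataset> %d patients x %d waves; %s epochs\n",
              n, x$config$n_waves,
              if (is.null(x$epochs)) "no" else format(nrow(x$epochs), big.mark = ",")))
  print(x$flow)
  invisible(x)
}

#' Write a cohort dataset to plain-text files
#'
#' Writes `panel.csv`, `items.csv`, `flow.json` and (when present)
#' `epochs.csv` (patient_id, ISO-8601 timestamp, MET, missing flag) into
#' `dir`.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "panel.csv")
  utils::write.csv(dataset$panel, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "items.csv")
  utils::write.csv(dataset$items, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "flow.json")
  jsonlite::write_json(dataset$flow, f, dataframe = "rows", pretty = TRUE)
  files <- c(files, f)
  if (!is.null(dataset$epochs)) {
    ep <- dataset$epochs
    ep$timestamp <- format(ep$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    f <- file.path(dir, "epochs.csv")
    utils::write.csv(ep, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
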