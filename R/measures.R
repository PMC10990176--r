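# From raw epoch streams and questionnaire items to the 8 analysis variables.

#' MET intensity cutpoints
#'
#' Light activity lies strictly below 3 MET, moderate in the closed interval
#' \[3, 6\], heavy strictly above 6 (boundaries assigned so the three printed
#' bands partition the line). A sedentary cutpoint (default 1.5 MET) below
#' which epochs are not counted as activity at all is a package choice:
#' without it, resting time would count as light activity.
#'
#' @param sedentary_max MET at or below which an epoch is sedentary.
#' @param light_max upper edge of light activity (default 3).
#' @param moderate_max upper edge of moderate activity (default 6).
#' @return A validated list of class `cutpoints`.
#' @export
cutpoints <- function(sedentary_max = 1.5, light_max = 3, moderate_max = 6) {
  assert_number(sedentary_max, "sedentary_max", lower = 0)
  assert_number(light_max, "light_max")
  assert_number(moderate_max, "moderate_max")
  if (!(sedentary_max < light_max && light_max < moderate_max)) {
    stop("cutpoints must satisfy sedentary_max < light_max < moderate_max")
  }
  structure(list(sedentary_max = sedentary_max, light_max = light_max,
                 moderate_max = moderate_max), class = "cutpoints")
}

#' Categorize epochs by MET intensity
#'
#' @param met nonnegative MET value(s).
#' @param cuts a [cutpoints()].
#' @return Factor with levels `sedentary`, `light`, `moderate`, `heavy`.
#' @export
categorize_epoch <- function(met, cuts = cutpoints()) {
  if (any(!is.finite(met)) || any(met < 0)) {
    stop("MET values must be finite and nonnegative")
  }
  lab <- ifelse(met <= cuts$sedentary_max, "sedentary",
                ifelse(met < cuts$light_max, "light",
                       ifelse(met <= cuts$moderate_max, "moderate", "heavy")))
  factor(lab, levels = c("sedentary", "light", "moderate", "heavy"))
}

#' Summarize one day of epochs into category minutes
#'
#' Category minutes are the epoch count per category times the epoch length;
#' sedentary time is excluded from every activity category and from the
#' total. Epochs flagged missing (column `missing`) are skipped.
#'
#' @param epochs tibble/data frame with `timestamp` and `met` (optionally
#'   `missing`), all on one calendar date.
#' @param cuts a [cutpoints()].
#' @param epoch_minutes epoch length in minutes.
#' @return A one-row [tibble::tibble()]: `date`, `minutes_light`,
#'   `minutes_moderate`, `minutes_heavy`, `minutes_total`.
#' @export
summarize_day <- function(epochs, cuts = cutpoints(), epoch_minutes = 1) {
  if (nrow(epochs) == 0) {
    return(tibble::tibble(date = as.Date(NA), minutes_light = 0,
                          minutes_moderate = 0, minutes_heavy = 0,
                          minutes_total = 0))
  }
  dates <- unique(as.Date(epochs$timestamp, tz = "UTC"))
  if (length(dates) > 1) {
    stop("epochs span more than one calendar date; summarize per day")
  }
  if ("missing" %in% names(epochs)) {
    epochs <- epochs[!epochs$missing, , drop = FALSE]
  }
  cat <- categorize_epoch(epochs$met, cuts)
  counts <- table(cat)
  light <- counts[["light"]] * epoch_minutes
  moderate <- counts[["moderate"]] * epoch_minutes
  heavy <- counts[["heavy"]] * epoch_minutes
  tibble::tibble(date = dates, minutes_light = light,
                 minutes_moderate = moderate, minutes_heavy = heavy,
                 minutes_total = light + moderate + heavy)
}

#' Summarize a multi-day epoch stream into daily summaries
#'
#' @inheritParams summarize_day
#' @return A [tibble::tibble()] of daily summaries, one row per calendar date
#'   present in the stream, ordered by date.
#' @export
summarize_days <- function(epochs, cuts = cutpoints(), epoch_minutes = 1) {
  d <- as.Date(epochs$timestamp, tz = "UTC")
  parts <- split(seq_len(nrow(epochs)), d)
  out <- lapply(parts, function(ix) {
    summarize_day(epochs[ix, , drop = FALSE], cuts, epoch_minutes)
  })
  res <- do.call(rbind, out)
  res[order(res$date), ]
}

#' Average daily summaries over 7-day post-discharge windows
#'
#' Week `w` covers days `7(w-1)+1 .. 7w` after discharge (day 1 = discharge
#' day). The mean is taken over the days actually available in the window; a
#' week with no available day yields `NA`, never zero.
#'
#' @param days daily summaries (see [summarize_days()]); rows with `NA`
#'   minutes count as unavailable.
#' @param weeks week indices to summarize.
#' @param start_date discharge date; defaults to the earliest date present.
#' @return A [tibble::tibble()] with one row per requested week.
#' @export
weekly_average <- function(days, weeks = 1:12, start_date = min(days$date)) {
  stopifnot(nrow(days) >= 1)
  day_index <- as.integer(as.Date(days$date) - as.Date(start_date)) + 1L
  cols <- c("minutes_light", "minutes_moderate", "minutes_heavy", "minutes_total")
  out <- lapply(weeks, function(w) {
    sel <- day_index >= 7 * (w - 1) + 1 & day_index <= 7 * w
    block <- days[sel, cols, drop = FALSE]
    block <- block[stats::complete.cases(block), , drop = FALSE]
    if (nrow(block) == 0) {
      vals <- rep(NA_real_, 4)
    } else {
      vals <- colMeans(block)
    }
    tibble::tibble(week = w, minutes_light = vals[1],
                   minutes_moderate = vals[2], minutes_heavy = vals[3],
                   minutes_total = vals[4])
  })
  do.call(rbind, out)
}

#' Extract wave-level activity from weekly summaries
#'
#' Waves take weeks 1, 3, 6 and 12 (the measurement occasions); other weeks
#' are retained only for reporting elsewhere. A week absent from the input or
#' entirely missing propagates `NA` to its wave.
#'
#' @param weekly output of [weekly_average()].
#' @param wave_weeks week indices defining the waves.
#' @return A [tibble::tibble()] with `wave`, `week`, `pa_light`,
#'   `pa_moderate`, `pa_heavy`, `pa_total`.
#' @export
extract_wave_pa <- function(weekly, wave_weeks = c(1, 3, 6, 12)) {
  ix <- match(wave_weeks, weekly$week)
  get <- function(col) {
    ifelse(is.na(ix), NA_real_, weekly[[col]][ix])
  }
  tibble::tibble(
    wave = seq_along(wave_weeks), week = wave_weeks,
    pa_light = get("minutes_light"), pa_moderate = get("minutes_moderate"),
    pa_heavy = get("minutes_heavy"), pa_total = get("minutes_total")
  )
}

#' Score the 13-item kinesiophobia questionnaire
#'
#' @param items 13 integer item scores in 1..4, or a matrix with 13 columns
#'   (one row per response set).
#' @return Integer total(s) in 13..52.
#' @export
score_tsk <- function(items) {
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1)
  if (ncol(m) != 13) {
    stop(sprintf("expected 13 items, got %d", ncol(m)))
  }
  bad <- which(!is.finite(m) | m != round(m) | m < 1 | m > 4, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("item %d out of range 1..4 (row %d)", bad[1, 2], bad[1, 1]))
  }
  tot <- as.integer(rowSums(m))
  if (!is.matrix(items)) tot[1] else tot
}

#' Severity band of a kinesiophobia total
#'
#' Bands as printed, endpoints inclusive: subclinical 13-22, mild 23-32,
#' moderate 33-42, severe 43-52.
#'
#' @param total total score(s) in \[13, 52\].
#' @return Factor with levels `subclinical`, `mild`, `moderate`, `severe`.
#' @export
categorize_tsk <- function(total) {
  if (any(!is.finite(total)) || any(total < 13) || any(total > 52)) {
    stop("`total` must lie in [13, 52]")
  }
  lev <- c("subclinical", "mild", "moderate", "severe")
  factor(lev[findInterval(total, c(13, 23, 33, 43))], levels = lev)
}

#' Build a wave panel from item tables and weekly activity
#'
#' Re-scores the questionnaire items and joins wave-level activity, producing
#' the long analysis panel; the item mask propagates to `tsk_missing`.
#'
#' @param items item table as in [generate_cohort()] output.
#' @param wave_pa per-patient wave activity: tibble with `patient_id`,
#'   `wave`, `pa_light`, `pa_moderate`, `pa_heavy`, `pa_total`.
#' @param wave_weeks week indices of the waves.
#' @return A long wave-panel [tibble::tibble()].
#' @export
build_wave_panel <- function(items, wave_pa, wave_weeks = c(1, 3, 6, 12)) {
  it <- as.data.frame(items)
  score <- rep(NA_integer_, nrow(it))
  ok <- stats::complete.cases(it[, paste0("item_", 1:13)])
  if (any(ok)) {
    score[ok] <- score_tsk(as.matrix(it[ok, paste0("item_", 1:13)]))
  }
  panel <- tibble::tibble(
    patient_id = it$patient_id, wave = it$wave,
    week = wave_weeks[it$wave],
    tsk_total = as.numeric(score),
    tsk_missing = !ok
  )
  pa <- as.data.frame(wave_pa)
  key <- paste(panel$patient_id, panel$wave)
  ix <- match(key, paste(pa$patient_id, pa$wave))
  for (col in c("pa_light", "pa_moderate", "pa_heavy", "pa_total")) {
    panel[[col]] <- pa[[col]][ix]
  }
  panel$pa_missing <- is.na(panel$pa_total)
  panel[order(panel$patient_id, panel$wave), ]
}
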