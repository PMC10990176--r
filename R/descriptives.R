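# Descriptive statistics: rank correlation with Fisher-z intervals, paired
# and independent rank tests with exact small-sample null distributions, and
# median/IQR summaries.

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Average ranks for ties; interval via the Fisher transform with variance
#' `1.06/(n-3)`. Magnitude bands on the absolute value: small up to 0.30,
#' medium above 0.30 up to 0.50, large above 0.50.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @param level confidence level.
#' @return List: `rho`, `lower`, `upper`, `n`, `magnitude`, `undefined` flag
#'   (constant input).
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, lower = NA_real_, upper = NA_real_, n = n,
                magnitude = NA_character_, undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  zse <- sqrt(1.06 / (n - 3))
  crit <- stats::qnorm(1 - (1 - level) / 2)
  a <- abs(rho)
  magnitude <- if (a <= 0.30) "small" else if (a <= 0.50) "medium" else "large"
  list(rho = rho, lower = tanh(z - crit * zse), upper = tanh(z + crit * zse),
       n = n, magnitude = magnitude, undefined = FALSE)
}

# Exact null distribution of a sum of independent sign-flipped weights via
# convolution (the shift algorithm). Weights must be nonnegative integers.
# Returns counts over achievable sums 0..sum(w).
signflip_counts <- function(w) {
  f <- numeric(sum(w) + 1)
  f[1] <- 1
  for (wi in w) {
    if (wi == 0) {
      f <- 2 * f
    } else {
      g <- f
      g[(wi + 1):length(f)] <- g[(wi + 1):length(f)] + f[1:(length(f) - wi)]
      f <- g
    }
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are handled by the Pratt convention: they enter the
#' ranking of absolute differences and are then discarded. For up to
#' `exact_limit` nonzero differences the null distribution is computed
#' exactly by convolution over the (tie-averaged) ranks — equivalent to
#' enumerating all sign assignments; beyond that a normal approximation with
#' the rank-based variance and a continuity correction is used. All
#' differences zero flags the test undefined.
#'
#' @param before,after paired numeric vectors.
#' @param exact_limit largest number of nonzero differences for the exact
#'   null.
#' @return List: `statistic` (positive-rank sum `V`), `p_value`, `n_nonzero`,
#'   `method`, `undefined` flag.
#' @export
wilcoxon_signed_rank <- function(before, after, exact_limit = 25) {
  keep <- stats::complete.cases(before, after)
  d <- (after - before)[keep]
  if (length(d) < 1) stop("need at least one complete pair")
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                method = "undefined", undefined = TRUE))
  }
  r_all <- rank(abs(d)) # Pratt: zeros ranked, then dropped
  nz <- d != 0
  r <- r_all[nz]
  V <- sum(r[d[nz] > 0])
  k <- sum(nz)
  if (k <= exact_limit) {
    w <- round(2 * r) # doubled average ranks are integers
    counts <- signflip_counts(w)
    tot <- sum(w)
    obs <- round(2 * V)
    denom <- 2^k
    p_le <- sum(counts[seq_len(obs + 1)]) / denom
    p_ge <- sum(counts[(obs + 1):(tot + 1)]) / denom
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sd <- sqrt(sum(r^2) / 4)
    z <- (V - mu - 0.5 * sign(V - mu)) / sd
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n_nonzero = as.integer(k),
       method = method, undefined = FALSE)
}

#' Mann-Whitney rank-sum test for two independent groups
#'
#' Exact null distribution (via the signed-rank-free Wilcoxon count
#' distribution) when there are no ties and both groups are small; otherwise
#' a normal approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_limit exact null used when both group sizes are at most this
#'   and no ties are present.
#' @return List: `statistic` (U for group_a), `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 25) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty")
  all_r <- rank(c(a, b))
  U <- sum(all_r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && na <= exact_limit && nb <= exact_limit) {
    p_le <- stats::pwilcox(U, na, nb)
    p_ge <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- na + nb
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    mu <- na * nb / 2
    sd <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    z <- if (sd == 0) 0 else (U - mu - 0.5 * sign(U - mu)) / sd
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p_value = min(p, 1), method = method)
}

#' Median and interquartile range
#'
#' Quartiles by the linear-interpolation rule by default; the rule is
#' switchable (and should be reported) because printed median/IQR values are
#' rule-sensitive.
#'
#' @param x numeric vector (`NA` dropped).
#' @param type quantile rule passed to [stats::quantile()].
#' @return List: `median`, `q1`, `q3`, `iqr`, `n`, `type`.
#' @export
median_iqr <- function(x, type = 7) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no non-missing values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       n = length(x), type = type)
}

#' Wave-level descriptive table for a cohort panel
#'
#' Median (IQR) of the kinesiophobia total and each activity category per
#' wave, severity-band counts, and the paired rank test comparing first
#' against last wave, mirroring a conventional characteristics table.
#'
#' @param panel long wave panel (see [generate_cohort()]).
#' @return List with `by_wave` (tibble), `severity` (tibble of band counts),
#'   `paired_tests` (tibble first vs last wave).
#' @export
describe_panel <- function(panel) {
  waves <- sort(unique(panel$wave))
  vars <- c("tsk_total", "pa_light", "pa_moderate", "pa_heavy", "pa_total")
  rows <- list()
  for (w in waves) {
    sub <- panel[panel$wave == w, ]
    for (v in vars) {
      if (all(is.na(sub[[v]]))) next
      s <- median_iqr(sub[[v]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        wave = w, week = sub$week[1], variable = v,
        median = s$median, iqr = s$iqr, n = s$n)
    }
  }
  by_wave <- do.call(rbind, rows)

  sev <- list()
  for (w in waves) {
    tot <- panel$tsk_total[panel$wave == w]
    tot <- tot[!is.na(tot)]
    tab <- table(categorize_tsk(tot))
    sev[[length(sev) + 1]] <- tibble::tibble(
      wave = w, band = names(tab), count = as.integer(tab),
      proportion = as.numeric(tab) / max(sum(tab), 1))
  }
  severity <- do.call(rbind, sev)

  w1 <- panel[panel$wave == min(waves), ]
  wl <- panel[panel$wave == max(waves), ]
  ids <- intersect(w1$patient_id, wl$patient_id)
  tests <- list()
  for (v in vars) {
    x1 <- w1[[v]][match(ids, w1$patient_id)]
    xl <- wl[[v]][match(ids, wl$patient_id)]
    keep <- stats::complete.cases(x1, xl)
    if (sum(keep) < 2 || all(x1[keep] == xl[keep])) next
    wt <- wilcoxon_signed_rank(x1[keep], xl[keep])
    tests[[length(tests) + 1]] <- tibble::tibble(
      variable = v,
      median_first = stats::median(x1[keep]), median_last = stats::median(xl[keep]),
      statistic = wt$statistic, p_value = wt$p_value, method = wt$method)
  }
  list(by_wave = by_wave, severity = severity,
       paired_tests = do.call(rbind, tests))
}

#' Cross-wave rank-correlation table
#'
#' Spearman correlations between the kinesiophobia total at each wave and
#' each activity category at each wave, on pairwise-complete observations
#' (the conventional pre-imputation workflow).
#'
#' @param panel long wave panel.
#' @return A [tibble::tibble()] with one row per (activity variable, activity
#'   wave, TSK wave) combination: `rho`, `lower`, `upper`, `n`, `magnitude`.
#' @export
correlation_table <- function(panel) {
  wide <- as.data.frame(panel)
  waves <- sort(unique(panel$wave))
  rows <- list()
  for (v in c("pa_light", "pa_moderate", "pa_heavy")) {
    for (wv in waves) {
      for (wt in waves) {
        x <- wide[[v]][wide$wave == wv]
        y <- wide$tsk_total[wide$wave == wt]
        if (sum(stats::complete.cases(x, y)) < 4) next
        s <- spearman_ci(x, y)
        rows[[length(rows) + 1]] <- tibble::tibble(
          pa_variable = v, pa_wave = wv, tsk_wave = wt,
          rho = s$rho, lower = s$lower, upper = s$upper, n = s$n,
          magnitude = s$magnitude)
      }
    }
  }
  do.call(rbind, rows)
}
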