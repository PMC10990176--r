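# Builders for the two competing panel models, and model-based reporting.

panel_var_names <- function(n_waves) {
  list(tsk = paste0("tsk_w", seq_len(n_waves)),
       pa = paste0("pa_w", seq_len(n_waves)))
}

#' Options for the panel-model builders
#'
#' @param n_waves number of measurement occasions (default 4: weeks 1, 3, 6,
#'   12 after discharge).
#' @param cross_lags include the cross-lagged paths between processes?
#' @param dynamic_residual_covariances free the within-wave residual
#'   covariances at waves 2+ (default off: fixed to zero, the variant
#'   consistent with 12 model degrees of freedom at 4 waves)?
#' @param ri_covariance free the covariance between the two random
#'   intercepts?
#' @return A list of class `riclpm_options`.
#' @export
riclpm_options <- function(n_waves = 4, cross_lags = TRUE,
                           dynamic_residual_covariances = FALSE,
                           ri_covariance = TRUE) {
  n_waves <- assert_count(n_waves, "n_waves", lower = 2)
  structure(list(n_waves = n_waves, cross_lags = isTRUE(cross_lags),
                 dynamic_residual_covariances = isTRUE(dynamic_residual_covariances),
                 ri_covariance = isTRUE(ri_covariance)),
            class = "riclpm_options")
}

#' Build the random-intercept cross-lagged panel model
#'
#' Two observed indicators per wave (kinesiophobia total, total activity
#' minutes/day). Each observed score is the sum of a grand mean (free), a
#' process-specific random intercept (latent, all loadings fixed to 1), and a
#' latent within-person component. Wave-1 within variances and their
#' covariance are free; each wave-to-wave transition carries two free
#' autoregressive and (by default) two free cross-lagged paths plus two free
#' within residual variances; within-wave residual covariances at waves 2+ are
#' fixed to zero under the defaults; random-intercept variances and covariance
#' are free. At 4 waves the default free-parameter count is 32, giving 12
#' model degrees of freedom.
#'
#' @param opts a [riclpm_options()] list.
#' @return A [path_model()] with a `report` attribute describing the
#'   Table-style row ordering used by [fit_panel()].
#' @export
build_riclpm <- function(opts = riclpm_options()) {
  nw <- opts$n_waves
  v <- panel_var_names(nw)
  wt <- paste0("w_tsk_", seq_len(nw))
  wp <- paste0("w_pa_", seq_len(nw))
  m <- path_model(observed = c(v$tsk, v$pa),
                  latent = c("ri_tsk", "ri_pa", wt, wp))
  for (t in seq_len(nw)) {
    m <- add_path(m, "ri_tsk", v$tsk[t], value = 1)
    m <- add_path(m, "ri_pa", v$pa[t], value = 1)
    m <- add_path(m, wt[t], v$tsk[t], value = 1)
    m <- add_path(m, wp[t], v$pa[t], value = 1)
    m <- add_mean(m, v$tsk[t], label = paste0("mu_tsk_", t))
    m <- add_mean(m, v$pa[t], label = paste0("mu_pa_", t))
  }
  m <- add_cov(m, "ri_tsk", "ri_tsk", label = "ri_var_tsk")
  m <- add_cov(m, "ri_pa", "ri_pa", label = "ri_var_pa")
  m <- if (opts$ri_covariance) {
    add_cov(m, "ri_tsk", "ri_pa", label = "ri_cov")
  } else {
    add_cov(m, "ri_tsk", "ri_pa", value = 0)
  }
  m <- add_cov(m, wt[1], wt[1], label = "w1_var_tsk")
  m <- add_cov(m, wp[1], wp[1], label = "w1_var_pa")
  m <- add_cov(m, wt[1], wp[1], label = "w1_cov")
  for (t in seq_len(nw - 1)) {
    m <- add_path(m, wt[t], wt[t + 1], label = paste0("a_tsk_t", t))
    m <- add_path(m, wp[t], wp[t + 1], label = paste0("a_pa_t", t))
    if (opts$cross_lags) {
      m <- add_path(m, wp[t], wt[t + 1], label = paste0("c_tsk_pa_t", t))
      m <- add_path(m, wt[t], wp[t + 1], label = paste0("c_pa_tsk_t", t))
    }
    m <- add_cov(m, wt[t + 1], wt[t + 1], label = paste0("rv_tsk_t", t))
    m <- add_cov(m, wp[t + 1], wp[t + 1], label = paste0("rv_pa_t", t))
    m <- if (opts$dynamic_residual_covariances) {
      add_cov(m, wt[t + 1], wp[t + 1], label = paste0("rcov_t", t))
    } else {
      add_cov(m, wt[t + 1], wp[t + 1], value = 0)
    }
  }
  # Table-3-style report order: dependent blocks (TSK wave 2..nw, then PA),
  # within a block the same-process lag first is NOT used -- the printed
  # table lists TSK row then PA row by independent variable order.
  rep_rows <- list()
  for (t in seq_len(nw - 1)) {
    rep_rows[[length(rep_rows) + 1]] <-
      data.frame(from = wt[t], to = wt[t + 1], block = paste0("tsk_w", t + 1))
    if (opts$cross_lags) {
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(from = wp[t], to = wt[t + 1], block = paste0("tsk_w", t + 1))
    }
  }
  for (t in seq_len(nw - 1)) {
    if (opts$cross_lags) {
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(from = wt[t], to = wp[t + 1], block = paste0("pa_w", t + 1))
    }
    rep_rows[[length(rep_rows) + 1]] <-
      data.frame(from = wp[t], to = wp[t + 1], block = paste0("pa_w", t + 1))
  }
  attr(m, "report") <- do.call(rbind, rep_rows)
  attr(m, "builder") <- "riclpm"
  m
}

#' Build the trait-kinesiophobia / autoregressive-activity model
#'
#' The alternative model: kinesiophobia is a pure random intercept (latent
#' trait with unit loadings and free per-wave residual variances, no
#' autoregression), activity is an observed AR(1) chain (free wave-1 variance,
#' free per-transition autoregressive paths and residual variances, no random
#' intercept), and the kinesiophobia residual covaries freely with the
#' activity disturbance within each wave (the association parameter whose
#' nullity is the substantive question). At 4 waves: 24 free parameters, 20
#' model degrees of freedom.
#'
#' @inheritParams build_riclpm
#' @param concurrent_covariances free within-wave kinesiophobia-activity
#'   covariances (default on; switching off raises df by `n_waves`).
#' @return A [path_model()] with a `report` attribute.
#' @export
build_ri_ar <- function(opts = riclpm_options(), concurrent_covariances = TRUE) {
  nw <- opts$n_waves
  v <- panel_var_names(nw)
  m <- path_model(observed = c(v$tsk, v$pa), latent = "ri_tsk")
  for (t in seq_len(nw)) {
    m <- add_path(m, "ri_tsk", v$tsk[t], value = 1)
    m <- add_cov(m, v$tsk[t], v$tsk[t], label = paste0("ev_tsk_", t))
    m <- add_mean(m, v$tsk[t], label = paste0("mu_tsk_", t))
    m <- add_mean(m, v$pa[t], label = paste0("mu_pa_", t))
    if (concurrent_covariances) {
      m <- add_cov(m, v$tsk[t], v$pa[t], label = paste0("cc_w", t))
    }
  }
  m <- add_cov(m, "ri_tsk", "ri_tsk", label = "ri_var_tsk")
  m <- add_cov(m, v$pa[1], v$pa[1], label = "pa_var_1")
  for (t in seq_len(nw - 1)) {
    m <- add_path(m, v$pa[t], v$pa[t + 1], label = paste0("a_pa_t", t))
    m <- add_cov(m, v$pa[t + 1], v$pa[t + 1], label = paste0("rv_pa_t", t))
  }
  rep_rows <- rbind(
    data.frame(from = "ri_tsk", to = v$tsk, block = "ri_tsk"),
    data.frame(from = v$pa[-nw], to = v$pa[-1], block = "pa_ar")
  )
  attr(m, "report") <- rep_rows
  attr(m, "builder") <- "ri_ar"
  m
}

#' Free-parameter values of the RI-CLPM implied by generator truth
#'
#' Maps a [truth_params()] object onto the labels of [build_riclpm()] so the
#' model-implied moments of the builder can be compared against (or used in
#' place of) the synthetic generator's dependence structure.
#'
#' @param truth a [truth_params()] object.
#' @return Named numeric vector over the default builder's free labels.
#' @export
riclpm_values <- function(truth) {
  nw <- truth$n_waves
  vals <- c(
    stats::setNames(truth$grand_means$tsk, paste0("mu_tsk_", seq_len(nw))),
    stats::setNames(truth$grand_means$pa, paste0("mu_pa_", seq_len(nw))),
    ri_var_tsk = unname(truth$ri_variances[1]),
    ri_var_pa = unname(truth$ri_variances[2]),
    ri_cov = truth$ri_covariance,
    w1_var_tsk = truth$wave1_within_cov[1, 1],
    w1_var_pa = truth$wave1_within_cov[2, 2],
    w1_cov = truth$wave1_within_cov[1, 2]
  )
  for (t in seq_len(nw - 1)) {
    L <- truth$lagged_coefs[[t]]
    vals[paste0("a_tsk_t", t)] <- L[1, 1]
    vals[paste0("c_tsk_pa_t", t)] <- L[1, 2]
    vals[paste0("c_pa_tsk_t", t)] <- L[2, 1]
    vals[paste0("a_pa_t", t)] <- L[2, 2]
    vals[paste0("rv_tsk_t", t)] <- truth$residual_variances[[t]][1]
    vals[paste0("rv_pa_t", t)] <- truth$residual_variances[[t]][2]
  }
  vals
}

#' Label a standardized effect size
#'
#' Bands by absolute value: small below 0.30, moderate in `[0.30, 0.50)`,
#' large at or above 0.50 (the conventional print bands leave a gap between
#' 0.29 and 0.30, which is closed downward).
#'
#' @param beta standardized coefficient(s).
#' @return Character vector of labels.
#' @export
effect_size_label <- function(beta) {
  if (any(!is.finite(beta))) stop("`beta` must be finite")
  a <- abs(beta)
  ifelse(a < 0.30, "small", ifelse(a < 0.50, "moderate", "large"))
}

#' Convert a long wave panel to the wide 8-column analysis table
#'
#' @param panel a long wave panel (columns `patient_id`, `wave`, `tsk_total`,
#'   `pa_total`) as produced by [generate_cohort()], or an already-wide
#'   numeric table which is returned as-is.
#' @param n_waves number of waves.
#' @return A numeric matrix with columns `tsk_w1..tsk_w<nw>, pa_w1..pa_w<nw>`,
#'   one row per patient, `NA` for missing cells.
#' @export
panel_wide <- function(panel, n_waves = 4) {
  v <- panel_var_names(n_waves)
  want <- c(v$tsk, v$pa)
  if (all(want %in% colnames(panel))) {
    return(as.matrix(as.data.frame(panel)[, want, drop = FALSE]))
  }
  stopifnot(all(c("patient_id", "wave", "tsk_total", "pa_total") %in%
                  colnames(panel)))
  panel <- as.data.frame(panel)
  ids <- unique(panel$patient_id)
  out <- matrix(NA_real_, length(ids), 2 * n_waves,
                dimnames = list(NULL, want))
  row_of <- match(panel$patient_id, ids)
  for (t in seq_len(n_waves)) {
    sel <- panel$wave == t
    out[row_of[sel], v$tsk[t]] <- panel$tsk_total[sel]
    out[row_of[sel], v$pa[t]] <- panel$pa_total[sel]
  }
  out
}

#' Fit a panel model to a wave panel, optionally over multiple imputations
#'
#' Without imputations, a single complete-case [fit_ml()] is run. With an
#' imputation set, the model is fitted to each completed table and pooled:
#' point estimates and SEs by Rubin's rules ([rubin_pool()]) per parameter,
#' standardized coefficients likewise, while the chi-square and CFI/TLI are
#' reported as the across-imputation mean with its spread (no consensus
#' pooling rule exists for fit statistics; the report labels this).
#'
#' @param model a builder output ([build_riclpm()] / [build_ri_ar()]) or any
#'   [path_model()] over the panel's 8 columns.
#' @param panel long or wide panel, see [panel_wide()]. Ignored when
#'   `imputations` is supplied.
#' @param imputations optional `imputation_set` from [fcs_impute()] whose
#'   completed tables are wide panels.
#' @param ... passed on to [fit_ml()].
#' @return A list of class `panel_fit`: `table` (tibble shaped like the
#'   published model tables: one row per reported path with standardized
#'   estimate, CI, SE, est/SE, p, and effect-size label), `fit`
#'   (chi-square/df/p/CFI/TLI, with across-imputation SDs when pooled),
#'   `fits` (the underlying `sem_fit` objects), and `pooled` flag.
#' @export
fit_panel <- function(model, panel = NULL, imputations = NULL, ...) {
  nw <- sum(startsWith(model$observed, "tsk_w"))
  if (is.null(imputations)) {
    stopifnot(!is.null(panel))
    fits <- list(fit_ml(model, panel_wide(panel, nw), ...))
    failures <- 0L
  } else {
    stopifnot(inherits(imputations, "imputation_set"))
    fits <- list()
    failures <- 0L
    for (im in imputations$imputations) {
      f <- tryCatch(fit_ml(model, panel_wide(im, nw), ...),
                    error = function(e) NULL)
      if (is.null(f)) failures <- failures + 1L else fits[[length(fits) + 1]] <- f
    }
    if (length(fits) < 2) {
      stop(sprintf("fit failed on %d of %d imputations; cannot pool", failures,
                   length(imputations$imputations)))
    }
    if (failures > 0) {
      warning(sprintf("fit failed on %d imputation(s); pooled over %d",
                      failures, length(fits)))
    }
  }
  pooled <- length(fits) > 1

  report <- attr(model, "report")
  if (is.null(report)) {
    report <- model$paths[!is.na(model$paths$label), c("from", "to")]
    report$block <- report$to
  }
  key <- function(df) paste(df$from, df$to)
  rows <- lapply(fits, function(f) {
    s <- f$standardized
    s[match(key(report), key(s)), , drop = FALSE]
  })

  m <- length(fits)
  if (!pooled) {
    s <- rows[[1]]
    std <- s$std; std_se <- s$std_se
    est <- s$estimate
  } else {
    std_mat <- sapply(rows, `[[`, "std")
    se_mat <- sapply(rows, `[[`, "std_se")
    est_mat <- sapply(rows, `[[`, "estimate")
    # pool each parameter over the imputations with finite uncertainty
    # (near-singular information can void the SE of an individual fit)
    pooled_rows <- lapply(seq_len(nrow(report)), function(i) {
      e <- std_mat[i, ]
      v <- se_mat[i, ]^2
      ok <- is.finite(e) & is.finite(v)
      if (sum(ok) < 2) {
        return(list(estimate = mean(e[is.finite(e)]), se = NA_real_))
      }
      rubin_pool(e[ok], v[ok])
    })
    std <- vapply(pooled_rows, `[[`, numeric(1), "estimate")
    std_se <- vapply(pooled_rows, `[[`, numeric(1), "se")
    est <- rowMeans(est_mat)
  }
  zval <- std / std_se
  tab <- tibble::tibble(
    block = report$block, from = report$from, to = report$to,
    estimate = est, std = std, se = std_se,
    lower = std - stats::qnorm(0.975) * std_se,
    upper = std + stats::qnorm(0.975) * std_se,
    est_over_se = zval,
    p_value = 2 * stats::pnorm(-abs(zval)),
    magnitude = ifelse(is.finite(std), effect_size_label(ifelse(is.finite(std), std, 0)), NA)
  )

  stat <- function(fn) vapply(fits, fn, numeric(1))
  fitstats <- list(
    chisq = mean(stat(function(f) f$chisq)),
    chisq_sd = if (pooled) stats::sd(stat(function(f) f$chisq)) else NA_real_,
    df = fits[[1]]$df,
    p_value = mean(stat(function(f) f$p_value)),
    cfi = mean(stat(function(f) f$cfi)),
    tli = mean(stat(function(f) f$tli)),
    cfi_sd = if (pooled) stats::sd(stat(function(f) f$cfi)) else NA_real_,
    tli_sd = if (pooled) stats::sd(stat(function(f) f$tli)) else NA_real_,
    n = fits[[1]]$n,
    m = m, failures = failures,
    note = if (pooled)
      "chi-square/CFI/TLI are across-imputation means (no standard pooling rule); estimates and SEs are Rubin-pooled"
    else NA_character_
  )
  structure(list(table = tab, fit = fitstats, fits = fits, pooled = pooled,
                 builder = attr(model, "builder") %||% "custom"),
            class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<panel_fit> %s model, n = %d%s\n", x$builder, x$fit$n,
              if (x$pooled) sprintf(", pooled over %d imputations", x$fit$m) else ""))
  cat(sprintf("  chi-square = %.*f (df = %d, p = %s), CFI = %.2f, TLI = %.2f\n",
              digits, x$fit$chisq, x$fit$df,
              format.pval(x$fit$p_value, digits = 2), x$fit$cfi, x$fit$tli))
  print(x$table, n = nrow(x$table))
  invisible(x)
}
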