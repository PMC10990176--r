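# Maximum-likelihood fitting of path models to sample moments.

#' Coerce raw data or a moments list to sample moments
#'
#' Accepts either a list with elements `mean`, `cov`, `n`, or a numeric
#' matrix/data frame of raw observations. Raw input is reduced to
#' complete-case sample moments (covariance with the `n - 1` denominator);
#' rows with any missing value are dropped — impute first if that matters
#' (see [fcs_impute()]).
#'
#' @param sample moments list or raw data.
#' @return A list with `mean`, `cov`, `n`.
#' @export
as_sample_moments <- function(sample) {
  if (is.list(sample) && !is.data.frame(sample) &&
      all(c("mean", "cov", "n") %in% names(sample))) {
    m <- sample$mean
    S <- as.matrix(sample$cov)
    check_spd(S, "sample covariance", strict = TRUE)
    stopifnot(length(m) == nrow(S))
    return(list(mean = m, cov = S, n = assert_count(sample$n, "n", lower = 2)))
  }
  x <- as.matrix(sample)
  if (!is.numeric(x)) stop("raw data must be numeric")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 complete rows")
  list(mean = colMeans(x), cov = stats::cov(x), n = nrow(x))
}

# Align sample moments to the model's observed order (when named).
align_sample <- function(model, smp) {
  vars <- model$observed
  nm <- names(smp$mean) %||% colnames(smp$cov)
  if (!is.null(nm)) {
    if (!all(vars %in% nm)) {
      stop("sample is missing observed variable(s): ",
           paste(setdiff(vars, nm), collapse = ", "))
    }
    smp$mean <- smp$mean[vars]
    smp$cov <- smp$cov[vars, vars, drop = FALSE]
  } else if (length(smp$mean) != length(vars)) {
    stop("unnamed sample dimension does not match the model's observed nodes")
  }
  smp
}

# Start values and optimizer scales. Observed variances/means seed the free
# variance/mean labels (latent variances take half the variance of an
# observed child reached through fixed unit loadings); paths and covariances
# start at 0. Parameter scales derive from per-node SD proxies so BFGS sees
# comparably scaled coordinates: s_i*s_j for a covariance, s_i/s_j for a
# path, s_i for a mean.
start_values <- function(model, cm, S, mbar) {
  labs <- cm$labels
  start <- stats::setNames(rep(0, length(labs)), labs)
  scale <- stats::setNames(rep(1, length(labs)), labs)
  obs_var <- stats::setNames(diag(S), model$observed)
  obs_mean <- stats::setNames(mbar, model$observed)
  fallback_var <- mean(diag(S))
  unit_children <- function(node) {
    p <- model$paths
    kids <- p$to[p$from == node & is.na(p$label) & p$value == 1]
    obs <- intersect(kids, model$observed)
    if (length(obs)) return(obs)
    out <- character()
    for (kkid in kids) out <- c(out, unit_children(kkid))
    out
  }
  node_var <- function(node) {
    if (node %in% model$observed) return(obs_var[[node]])
    kids <- unit_children(node)
    if (length(kids)) 0.5 * mean(obs_var[kids]) else 0.5 * fallback_var
  }
  for (r in seq_len(nrow(model$covs))) {
    lab <- model$covs$label[r]
    if (is.na(lab)) next
    n1 <- model$covs$node1[r]; n2 <- model$covs$node2[r]
    if (n1 == n2 && start[lab] == 0) start[lab] <- node_var(n1)
    scale[lab] <- sqrt(node_var(n1) * node_var(n2))
  }
  for (r in seq_len(nrow(model$paths))) {
    lab <- model$paths$label[r]
    if (is.na(lab)) next
    scale[lab] <- sqrt(node_var(model$paths$to[r]) /
                         max(node_var(model$paths$from[r]), 1e-12))
  }
  for (r in seq_len(nrow(model$means))) {
    lab <- model$means$label[r]
    if (is.na(lab)) next
    node <- model$means$node[r]
    if (node %in% model$observed && start[lab] == 0) {
      start[lab] <- obs_mean[[node]]
    }
    scale[lab] <- sqrt(node_var(node))
  }
  list(start = start, scale = pmax(scale, 1e-6))
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p + (m - mu)' Sigma^-1 (m - mu)`
#' over the free parameters with quasi-Newton (BFGS) iterations, starting from
#' documented start values, with up to `max_restarts` seeded jittered restarts
#' on non-convergence. Non-positive-definite implied covariances encountered
#' during the search are rejected by a barrier value, which the line search
#' then backs away from. The chi-square test statistic is `(n-1) * F` at the
#' minimum (a `multiplier = "n"` switch is provided since software conventions
#' differ); standard errors come from the inverse numerical Hessian of `F`,
#' scaled by `2/(n-1)`.
#'
#' @param model a [path_model()].
#' @param sample raw complete-case data or a `list(mean=, cov=, n=)`; see
#'   [as_sample_moments()].
#' @param se compute standard errors (numerical Hessian)?
#' @param standardized attach standardized path estimates via [standardize()]?
#' @param multiplier `"n-1"` (Wishart ML, default) or `"n"` chi-square scaling.
#' @param max_restarts jittered restarts attempted on non-convergence.
#' @param grad_tol convergence tolerance on the (scaled) gradient norm.
#' @param seed seed for restart jitter only (estimation itself is
#'   deterministic).
#' @return An object of class `sem_fit`: estimates, SEs, chi-square `chisq`,
#'   `df`, `p_value`, `cfi`/`tli` (with raw untruncated values alongside),
#'   log-likelihood, convergence diagnostics, and (optionally) the
#'   standardized solution.
#' @export
fit_ml <- function(model, sample, se = TRUE, standardized = se,
                   multiplier = c("n-1", "n"), max_restarts = 5L,
                   grad_tol = 1e-6, seed = 1L) {
  multiplier <- match.arg(multiplier)
  smp <- align_sample(model, as_sample_moments(sample))
  p <- length(model$observed)
  S <- unname(as.matrix(smp$cov))
  mbar <- unname(smp$mean)
  n <- smp$n
  if (n <= p) stop(sprintf("need n > p (n = %d, p = %d)", n, p))
  cS <- chol(S)
  logdetS <- 2 * sum(log(diag(cS)))
  cm <- compile_path_model(model)
  oi <- cm$obs
  k <- cm$k
  Ik <- diag(k)
  BIG <- 1e10

  objective <- function(theta) {
    mats <- ram_matrices(cm, theta)
    total <- tryCatch(solve(Ik - mats$A), error = function(e) NULL)
    if (is.null(total)) return(BIG)
    V <- total[oi, , drop = FALSE]
    sig <- V %*% mats$S %*% t(V)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(BIG)
    siginv <- chol2inv(ch)
    d <- mbar - drop(V %*% mats$M)
    f <- 2 * sum(log(diag(ch))) - logdetS + sum(S * siginv) - p +
      drop(crossprod(d, siginv %*% d))
    if (!is.finite(f)) BIG else f
  }

  # Analytic gradient of F via RAM trace identities: with u = Sigma^-1 d and
  # W = Sigma^-1 - Sigma^-1 (S + d d') Sigma^-1,
  #   dF/dA[i,j] = 2 (SigmaFull[,obs] W V)[j,i] - 2 s[i] muFull[j],
  #   dF/dS[i,j] = (V' W V)[j,i]  (off-diagonal entries appear twice),
  #   dF/dM[i]   = -2 s[i],   s = V' u.
  gradient <- function(theta) {
    np_ <- length(theta)
    mats <- ram_matrices(cm, theta)
    total <- tryCatch(solve(Ik - mats$A), error = function(e) NULL)
    if (is.null(total)) return(numeric(np_))
    V <- total[oi, , drop = FALSE]
    SVt <- mats$S %*% t(V)
    sig <- V %*% SVt
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(numeric(np_))
    siginv <- chol2inv(ch)
    mu_full <- drop(total %*% mats$M)
    d <- mbar - mu_full[oi]
    u <- drop(siginv %*% d)
    W <- siginv - siginv %*% S %*% siginv - tcrossprod(u)
    WV <- W %*% V
    g <- numeric(np_)
    acc <- function(par, val) {
      if (length(par) == 0) return()
      t <- rowsum(val, par)
      ix <- as.integer(rownames(t))
      g[ix] <<- g[ix] + t[, 1]
    }
    if (length(cm$A_free_par)) {
      GA <- (total %*% SVt) %*% WV # SigmaFull[, obs] %*% WV, k x k
      s <- drop(crossprod(V, u))
      val <- 2 * (GA[cbind(cm$A_free_j, cm$A_free_i)] -
                    s[cm$A_free_i] * mu_full[cm$A_free_j])
      acc(cm$A_free_par, val)
    }
    if (length(cm$S_free_par)) {
      GS <- crossprod(V, WV)
      acc(cm$S_free_par, GS[cbind(cm$S_free_j, cm$S_free_i)])
    }
    if (length(cm$M_free_par)) {
      s2 <- drop(crossprod(V, u))
      acc(cm$M_free_par, -2 * s2[cm$M_free_pos])
    }
    g
  }

  sv <- start_values(model, cm, S, mbar)
  start <- sv$start
  np <- length(start)
  parscale <- unname(sv$scale)

  ctl <- list(maxit = 1000, reltol = 1e-14, parscale = parscale)
  run_from <- function(th0) {
    opt <- stats::optim(th0, objective, gr = gradient, method = "BFGS",
                        control = ctl)
    # polish: restarting BFGS resets its Hessian approximation and typically
    # drives the gradient a few more orders of magnitude down
    for (i in 1:2) {
      if (max(abs(gradient(opt$par) * parscale)) < grad_tol) break
      opt <- stats::optim(opt$par, objective, gr = gradient, method = "BFGS",
                          control = ctl)
    }
    g <- gradient(opt$par)
    list(par = opt$par, value = opt$value,
         gnorm = max(abs(g * parscale)),
         ok = opt$convergence == 0 && opt$value < BIG / 2)
  }

  best <- NULL
  restarts_used <- 0L
  for (r in 0:max_restarts) {
    th0 <- if (r == 0) {
      start
    } else {
      withr::with_seed(as.integer(seed) + r, {
        start * stats::runif(np, 0.7, 1.3) + stats::rnorm(np, 0, 0.05 * parscale)
      })
    }
    if (objective(th0) >= BIG / 2 && r > 0) next
    res <- run_from(th0)
    restarts_used <- r
    if (is.null(best) || res$value < best$value) best <- res
    if (best$ok && best$gnorm < max(grad_tol, 1e-4)) break
  }
  converged <- best$ok && best$gnorm < max(grad_tol, 1e-4)
  if (!converged) {
    warning(sprintf("fit_ml did not converge (scaled gradient norm %.2e)",
                    best$gnorm))
  }

  theta <- stats::setNames(best$par, cm$labels)
  fmin <- best$value
  mult <- if (multiplier == "n-1") n - 1 else n
  chisq <- mult * fmin
  df <- suppressWarnings(model_df(model))
  p_value <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_

  # observed-data log-likelihood at the optimum (biased-S convention)
  mom <- implied_moments(model, theta)
  sig <- unname(mom$sigma)
  siginv <- chol2inv(chol(sig))
  d <- mbar - unname(mom$mu)
  Sml <- S * (n - 1) / n
  loglik <- -(n / 2) * (p * log(2 * pi) + 2 * sum(log(diag(chol(sig)))) +
                          sum(Sml * siginv) + drop(crossprod(d, siginv %*% d)))

  base <- baseline_fit(list(mean = mbar, cov = S, n = n), multiplier = multiplier)
  idx <- fit_indices(chisq, df, base$chisq, base$df)

  out <- list(
    model = model, labels = cm$labels, estimates = theta,
    se = NULL, acov = NULL, fmin = fmin, loglik = loglik,
    chisq = chisq, df = df, p_value = p_value,
    baseline_chisq = base$chisq, baseline_df = base$df,
    cfi = idx$cfi, tli = idx$tli, cfi_raw = idx$cfi_raw, tli_raw = idx$tli_raw,
    n = n, p = p, multiplier = multiplier,
    converged = converged, gradient_norm = best$gnorm,
    restarts = restarts_used,
    sample = list(mean = mbar, cov = S, n = n),
    standardized = NULL
  )
  class(out) <- "sem_fit"

  if (se && length(theta)) {
    H <- stats::optimHess(best$par, objective,
                          control = list(parscale = parscale,
                                         ndeps = rep(1e-4, np)))
    acov <- tryCatch((2 / mult) * solve(H), error = function(e) NULL)
    if (is.null(acov)) {
      warning("information matrix is singular; using a pseudo-inverse for SEs")
      acov <- (2 / mult) * MASS::ginv(H)
    }
    dimnames(acov) <- list(cm$labels, cm$labels)
    vars <- diag(acov)
    if (any(vars < 0)) {
      warning("negative variance estimate(s) in the inverse information; SEs flagged NA")
      vars[vars < 0] <- NA_real_
    }
    out$acov <- acov
    out$se <- stats::setNames(sqrt(vars), cm$labels)
  }
  if (standardized) {
    out$standardized <- standardize(model, out)
  }
  out
}

#' Independence baseline fit
#'
#' The CFI/TLI baseline: all covariances zero, variances and means free. Its
#' ML solution is closed-form (`Sigma = diag(S)`, `mu = m`), so
#' `F_b = sum(log s_ii) - log|S|` and `T_b = (n-1) F_b`; `df_b = p(p+3)/2 - 2p`.
#'
#' @inheritParams fit_ml
#' @return A list with `chisq` and `df`.
#' @export
baseline_fit <- function(sample, multiplier = c("n-1", "n")) {
  multiplier <- match.arg(multiplier)
  smp <- as_sample_moments(sample)
  S <- unname(as.matrix(smp$cov))
  p <- nrow(S)
  f <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  mult <- if (multiplier == "n-1") smp$n - 1 else smp$n
  list(chisq = mult * f, df = as.integer(p * (p + 3) / 2 - 2 * p))
}

#' Incremental fit indices
#'
#' `cfi = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)` and
#' `tli = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)`. Untruncated values are
#' reported alongside the conventionally truncated ones; `df = 0` flags the
#' indices as undefined rather than returning numbers.
#'
#' @param chisq,df fitted model chi-square and degrees of freedom.
#' @param baseline_chisq,baseline_df independence-baseline chi-square and df.
#' @return List with `cfi`, `tli` (truncated to `[0, 1]`) and `cfi_raw`,
#'   `tli_raw`.
#' @export
fit_indices <- function(chisq, df, baseline_chisq, baseline_df) {
  if (baseline_df <= 0) stop("baseline degrees of freedom must be positive")
  if (df == 0) {
    out <- list(cfi = NA_real_, tli = NA_real_,
                cfi_raw = NA_real_, tli_raw = NA_real_)
    attr(out, "flag") <- "undefined: df = 0"
    return(out)
  }
  num <- max(chisq - df, 0)
  den <- max(baseline_chisq - baseline_df, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi_raw <- if (baseline_chisq - baseline_df == 0) NA_real_ else
    1 - (chisq - df) / (baseline_chisq - baseline_df)
  tli_raw <- ((baseline_chisq / baseline_df) - (chisq / df)) /
    ((baseline_chisq / baseline_df) - 1)
  list(cfi = min(max(cfi, 0), 1), tli = min(max(tli_raw, 0), 1),
       cfi_raw = cfi_raw, tli_raw = tli_raw)
}

#' Standardized path coefficients with delta-method confidence intervals
#'
#' Each path coefficient (free or fixed, e.g. unit factor loadings) is scaled
#' by `SD(source)/SD(target)`, with SDs taken from the implied covariance
#' extended over latent nodes. Confidence intervals follow from the delta
#' method: the numerical Jacobian of the standardized coefficients with
#' respect to the free parameters, sandwiched around the estimate covariance.
#'
#' @param model a [path_model()].
#' @param fit a `sem_fit` from [fit_ml()] (needs `acov` for CIs).
#' @param level confidence level.
#' @return A [tibble::tibble()] with columns `from`, `to`, `label`,
#'   `estimate`, `std`, `std_se`, `lower`, `upper`.
#' @export
standardize <- function(model, fit, level = 0.95) {
  cm <- compile_path_model(model)
  if (nrow(model$paths) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          label = character(), estimate = numeric(),
                          std = numeric(), std_se = numeric(),
                          lower = numeric(), upper = numeric()))
  }
  theta_hat <- unname(fit$estimates[cm$labels])
  k <- cm$k
  Ik <- diag(k)
  node_idx <- stats::setNames(seq_len(k), cm$nodes)
  pi_from <- node_idx[model$paths$from]
  pi_to <- node_idx[model$paths$to]
  p_free <- !is.na(model$paths$label)
  p_par <- match(model$paths$label, cm$labels)

  std_fun <- function(theta) {
    mats <- ram_matrices(cm, theta)
    total <- solve(Ik - mats$A)
    sigma_full <- total %*% mats$S %*% t(total)
    sdv <- sqrt(pmax(diag(sigma_full), 0))
    b <- model$paths$value
    b[p_free] <- theta[p_par[p_free]]
    out <- b * sdv[pi_from] / sdv[pi_to]
    out[sdv[pi_to] == 0] <- NA_real_
    out
  }

  est_unstd <- model$paths$value
  est_unstd[p_free] <- theta_hat[p_par[p_free]]
  std <- std_fun(theta_hat)
  std_se <- rep(NA_real_, length(std))
  if (!is.null(fit$acov) && length(theta_hat)) {
    J <- num_jacobian(std_fun, theta_hat)
    v <- diag(J %*% fit$acov %*% t(J))
    v[v < 0] <- NA_real_
    std_se <- sqrt(v)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    from = model$paths$from, to = model$paths$to,
    label = model$paths$label,
    estimate = est_unstd, std = std, std_se = std_se,
    lower = std - z * std_se, upper = std + z * std_se
  )
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<sem_fit> %d free parameters, n = %d, %s\n",
              length(x$labels), x$n,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  chi-square = %.*f, df = %d, p = %s\n", digits, x$chisq, x$df,
              format.pval(x$p_value, digits = digits)))
  cat(sprintf("  CFI = %.*f, TLI = %.*f (raw: %.*f, %.*f)\n",
              digits, x$cfi, digits, x$tli,
              digits, x$cfi_raw, digits, x$tli_raw))
  if (!is.null(x$standardized) && nrow(x$standardized)) {
    cat("  standardized paths:\n")
    print(x$standardized, n = 20)
  }
  invisible(x)
}
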