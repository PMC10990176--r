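# Little's MCAR test, chained-equations multiple imputation, Rubin pooling.

# EM estimation of a multivariate-normal mean/covariance from a rectangular
# table with missing entries, sweeping the missingness patterns.
em_norm <- function(Y, tol = 1e-8, max_iter = 500) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  obs <- !is.na(Y)
  pat_key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_key)

  mu <- colMeans(Y, na.rm = TRUE)
  sigma <- diag(apply(Y, 2, stats::var, na.rm = TRUE), p)
  ll_old <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (rows in pats) {
      o <- which(obs[rows[1], ])
      mset <- setdiff(seq_len(p), o)
      nj <- length(rows)
      Yj <- Y[rows, , drop = FALSE]
      if (length(o) == 0) {
        Yj[, ] <- rep(mu, each = nj)
        C <- sigma
      } else {
        Soo <- sigma[o, o, drop = FALSE]
        ch <- tryCatch(chol(Soo), error = function(e) NULL)
        if (is.null(ch)) {
          Soo <- Soo + diag(1e-8 * mean(diag(sigma)), length(o))
          ch <- chol(Soo)
        }
        Sooinv <- chol2inv(ch)
        dev <- sweep(Yj[, o, drop = FALSE], 2, mu[o])
        ll <- ll - 0.5 * (nj * (length(o) * log(2 * pi) +
                                  2 * sum(log(diag(ch)))) +
                            sum((dev %*% Sooinv) * dev))
        C <- matrix(0, p, p)
        if (length(mset) > 0) {
          reg <- sigma[mset, o, drop = FALSE] %*% Sooinv
          Yj[, mset] <- rep(mu[mset], each = nj) + dev %*% t(reg)
          C[mset, mset] <- sigma[mset, mset, drop = FALSE] -
            reg %*% sigma[o, mset, drop = FALSE]
        }
      }
      T1 <- T1 + colSums(Yj)
      T2 <- T2 + crossprod(Yj) + nj * C
    }
    mu <- T1 / n
    sigma <- T2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll, iterations = iter,
       converged = converged)
}

#' Little's test of missing completely at random
#'
#' Estimates the grand mean and covariance by EM, then compares each
#' missingness pattern's observed-variable means against the EM estimates:
#' `d2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^-1 (ybar_j - mu_j)` over the
#' observed variables of pattern `j`, referred to a chi-square with
#' `sum_j p_j - p` degrees of freedom. With a single pattern (complete data)
#' the statistic is 0 with 0 df and the test is flagged undefined.
#'
#' @param data numeric matrix or data frame; missing cells `NA`, or supply an
#'   explicit logical `mask` (TRUE = missing) of the same shape.
#' @param mask optional explicit missingness mask.
#' @param tol,max_iter EM convergence controls (absolute log-likelihood
#'   change below `tol`, default 1e-8, or `max_iter` sweeps).
#' @return A list of class `littles_mcar`: `statistic`, `df`, `p_value`,
#'   `n_patterns`, `undefined` flag, and the EM solution in `em`.
#' @export
littles_mcar <- function(data, mask = NULL, tol = 1e-8, max_iter = 500) {
  Y <- as.matrix(data)
  if (!is.numeric(Y)) stop("`data` must be numeric")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(Y)))
    Y[mask] <- NA
  }
  all_missing <- colSums(!is.na(Y)) == 0
  if (any(all_missing)) {
    warning("excluding variable(s) with no observed values: ",
            paste(colnames(Y)[all_missing] %||% which(all_missing),
                  collapse = ", "))
    Y <- Y[, !all_missing, drop = FALSE]
  }
  p <- ncol(Y)
  em <- em_norm(Y, tol = tol, max_iter = max_iter)
  obs <- !is.na(Y)
  pat_key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(nrow(Y)), pat_key)

  d2 <- 0
  sum_pj <- 0L
  for (rows in pats) {
    o <- which(obs[rows[1], ])
    if (length(o) == 0) next
    sum_pj <- sum_pj + length(o)
    ybar <- colMeans(Y[rows, o, drop = FALSE])
    Soo <- em$sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(Soo), error = function(e) NULL)
    if (is.null(ch)) {
      warning("singular pattern covariance; ridge-regularized")
      Soo <- Soo + diag(1e-8 * mean(diag(em$sigma)), length(o))
      ch <- chol(Soo)
    }
    dev <- ybar - em$mu[o]
    d2 <- d2 + length(rows) * drop(crossprod(dev, chol2inv(ch) %*% dev))
  }
  df <- sum_pj - p
  undefined <- df <= 0
  structure(
    list(statistic = d2, df = as.integer(df),
         p_value = if (undefined) NA_real_ else
           stats::pchisq(d2, df, lower.tail = FALSE),
         n_patterns = length(pats), undefined = undefined, em = em),
    class = "littles_mcar"
  )
}

#' @export
print.littles_mcar <- function(x, ...) {
  if (x$undefined) {
    cat("Little's MCAR test: undefined (single missingness pattern)\n")
  } else {
    cat(sprintf(
      "Little's MCAR test: chi-square = %.3f, df = %d, p = %s (%d patterns)\n",
      x$statistic, x$df, format.pval(x$p_value, digits = 3), x$n_patterns))
  }
  invisible(x)
}

# One Bayesian normal linear regression draw: noninformative prior,
# sigma^2 from the scaled inverse chi-square, beta from its normal posterior,
# then predictive draws for the missing rows.
bayes_lm_draw <- function(X_obs, y_obs, X_mis) {
  q <- ncol(X_obs)
  XtX <- crossprod(X_obs)
  ridge <- diag(1e-10 * max(diag(XtX), 1), q)
  ch <- tryCatch(chol(XtX), error = function(e) chol(XtX + ridge))
  XtXinv <- chol2inv(ch)
  beta_hat <- XtXinv %*% crossprod(X_obs, y_obs)
  resid <- y_obs - X_obs %*% beta_hat
  df <- max(nrow(X_obs) - q, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  beta <- beta_hat + sqrt(sigma2) * (t(chol(XtXinv)) %*% stats::rnorm(q))
  drop(X_mis %*% beta) + sqrt(sigma2) * stats::rnorm(nrow(X_mis))
}

#' Chained-equations multiple imputation (normal-linear kernel)
#'
#' Full conditional specification for continuous data: each incomplete
#' variable is regressed on all others with a Bayesian normal linear model
#' (noninformative prior), missing values replaced by posterior-predictive
#' draws, cycling `iterations` times per imputation. Observed cells are never
#' touched. Initial fills are random draws from each variable's observed
#' values.
#'
#' @param data numeric matrix or data frame with `NA` for missing cells.
#' @param m number of completed datasets (at least 2).
#' @param iterations chained-equation cycles per imputation.
#' @param seed integer seed (`NULL` for ambient stream).
#' @return A list of class `imputation_set`: `imputations` (list of `m`
#'   completed data frames), `mask`, `m`, `iterations`, `seed`.
#' @export
fcs_impute <- function(data, m = 20, iterations = 10, seed = NULL) {
  m <- assert_count(m, "m", lower = 2)
  iterations <- assert_count(iterations, "iterations", lower = 1)
  Y <- as.matrix(data)
  if (!is.numeric(Y)) {
    stop("all columns must be numeric; categorical imputation is out of scope")
  }
  mask <- is.na(Y)
  if (any(colSums(!mask) == 0)) {
    stop("variable(s) entirely missing cannot be imputed")
  }
  p <- ncol(Y)
  targets <- which(colSums(mask) > 0)
  targets <- targets[order(colSums(mask)[targets])] # least missing first
  with_seed_opt(seed, {
    imputations <- vector("list", m)
    for (im in seq_len(m)) {
      Z <- Y
      for (j in targets) {
        obs_vals <- Y[!mask[, j], j]
        Z[mask[, j], j] <- sample(obs_vals, sum(mask[, j]), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (j in targets) {
          pred <- setdiff(seq_len(p), j)
          X <- cbind(1, Z[, pred, drop = FALSE])
          oj <- !mask[, j]
          Z[mask[, j], j] <- bayes_lm_draw(X[oj, , drop = FALSE], Z[oj, j],
                                           X[mask[, j], , drop = FALSE])
        }
      }
      out <- as.data.frame(Z)
      if (!is.null(colnames(Y))) names(out) <- colnames(Y)
      imputations[[im]] <- out
    }
    structure(list(imputations = imputations, mask = mask, m = m,
                   iterations = iterations, seed = seed),
              class = "imputation_set")
  })
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed tables (%d x %d), %d chained cycles; %.1f%% cells imputed\n",
              x$m, nrow(x$mask), ncol(x$mask), x$iterations,
              100 * mean(x$mask)))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean; total variance is `W + (1 + 1/m) B` with `W`
#' the mean within-imputation variance and `B` the between-imputation
#' variance; degrees of freedom follow Rubin's small-sample formula
#' `(m - 1)(1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances per-imputation squared standard errors.
#' @param level confidence level for the interval.
#' @return List with `estimate`, `within`, `between`, `variance`, `se`, `df`,
#'   `lower`, `upper`, `m`.
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool")
  if (length(variances) != m || any(!is.finite(variances)) ||
      any(variances < 0)) {
    stop("`variances` must be m finite nonnegative reals")
  }
  if (any(!is.finite(estimates))) stop("`estimates` must be finite")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  se <- sqrt(total)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  list(estimate = qbar, within = W, between = B, variance = total, se = se,
       df = df, lower = qbar - tq * se, upper = qbar + tq * se, m = m)
}
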