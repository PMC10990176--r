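# Shared fixtures and independent oracles, built in code.

# Wide observed matrix from a latent panel draw.
panel_obs <- function(pan, n_waves = 4) {
  as.matrix(pan[, c(paste0("tsk_w", seq_len(n_waves)),
                    paste0("pa_w", seq_len(n_waves)))])
}

# Small, well-conditioned truth for quick fits.
quick_truth <- function(cross_lags = TRUE) {
  default_truth_params(cross_lags = cross_lags)
}

# Univariate AR(1) chain as a path model: stationary wave-1 variance
# q / (1 - b^2), free-less (all fixed) so implied moments are closed-form
# comparable.
ar1_model <- function(n_waves, b, q, mean = 0) {
  vars <- paste0("y", seq_len(n_waves))
  m <- path_model(observed = vars)
  m <- add_cov(m, vars[1], vars[1], value = q / (1 - b^2))
  m <- add_mean(m, vars[1], value = mean)
  for (t in seq_len(n_waves - 1)) {
    m <- add_path(m, vars[t], vars[t + 1], value = b)
    m <- add_cov(m, vars[t + 1], vars[t + 1], value = q)
    m <- add_mean(m, vars[t + 1], value = mean * (1 - b))
  }
  m
}

# Brute-force two-sided exact p for the signed-rank test with the Pratt
# zero convention: enumerate all sign assignments of the nonzero
# differences (feasible for k <= 12).
brute_signed_rank_p <- function(d) {
  r_all <- rank(abs(d))
  nz <- which(d != 0)
  r <- r_all[nz]
  v_obs <- sum(r[d[nz] > 0])
  k <- length(nz)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force two-sided exact p for the rank-sum test: enumerate all
# assignments of group labels (feasible for small groups).
brute_rank_sum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo standard errors for empirical moments of an 8-variable panel.
mc_se_cov <- function(sigma, n) {
  sqrt((outer(diag(sigma), diag(sigma)) + sigma^2) / n)
}
mc_se_mean <- function(sigma, n) sqrt(diag(sigma) / n)
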