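# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary seed; NULL seed means "use the ambient RNG
# stream" so that composite generators can seed once at the top.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_number(x, name, lower = lower)
  if (x != round(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be proportion(s) in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Symmetric PSD check via eigenvalues; `strict` demands positive definiteness.
check_spd <- function(m, name, strict = TRUE, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  ref <- max(abs(ev), 1)
  if (strict && min(ev) <= tol * ref) {
    stop(sprintf("`%s` is not positive definite (min eigenvalue %.3e)",
                 name, min(ev)), call. = FALSE)
  }
  if (!strict && min(ev) < -tol * ref) {
    stop(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3e)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(m)
}

# Multivariate normal draws through an eigen square root, so positive
# SEMI-definite covariances (e.g. zero random-intercept variance) are allowed.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  if (p == 1L) {
    return(matrix(mu + sqrt(max(sigma[1], 0)) * stats::rnorm(n), ncol = 1L))
  }
  e <- eigen(sigma, symmetric = TRUE)
  root <- sqrt(pmax(e$values, 0)) * t(e$vectors) # rows scaled
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% root, 2L, mu, `+`)
}

# Central finite-difference gradient.
num_grad <- function(f, x, h = NULL) {
  h <- h %||% (1e-6 * pmax(abs(x), 1))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h[i]
    xm[i] <- xm[i] - h[i]
    g[i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  g
}

# Central finite-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, h = NULL) {
  h <- h %||% (1e-5 * pmax(abs(x), 1))
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h[i]
    xm[i] <- xm[i] - h[i]
    J[, i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  J
}
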