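# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately re-derive results through a different algorithm than the
# package (Newton-Raphson instead of IRLS, Nelder-Mead instead of BFGS,
# explicit loops instead of matrix shortcuts).

# Newton-Raphson maximization of the Poisson log-likelihood with step
# halving; independent of the package's IRLS path.
nr_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
  loglik <- function(b) {
    eta <- X %*% b
    sum(y * eta - exp(eta))
  }
  ll <- loglik(beta)
  for (i in seq_len(maxit)) {
    mu <- as.numeric(exp(X %*% beta))
    score <- crossprod(X, y - mu)
    info <- crossprod(X * sqrt(mu))
    step <- solve(info, score)
    new_beta <- beta + step
    new_ll <- loglik(new_beta)
    halvings <- 0
    while (new_ll < ll && halvings < 50) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
      halvings <- halvings + 1
    }
    if (abs(new_ll - ll) < tol * (abs(ll) + 1)) {
      return(as.numeric(new_beta))
    }
    beta <- new_beta
    ll <- new_ll
  }
  as.numeric(beta)
}

# Quasi-variance objective minimized by an independent Nelder-Mead search
# (raw log-variance parametrization, no gradient, different start).
qvar_oracle <- function(contrast_cov) {
  V <- as.matrix(contrast_cov)
  m <- ncol(V)
  K <- m + 1
  D <- matrix(0, K, K)
  D[1, -1] <- diag(V); D[-1, 1] <- diag(V)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) D[i + 1, j + 1] <- V[i, i] + V[j, j] - 2 * V[i, j]
  }
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  logd <- log(D[pairs])
  obj <- function(w) {
    v <- exp(w)
    sum((log(v[pairs[, 1]] + v[pairs[, 2]]) - logd)^2)
  }
  w0 <- rep(log(mean(diag(V)) / 2), K)
  opt <- stats::optim(w0, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
  list(v = exp(opt$par), value = opt$value)
}

# A simulation config with every diabetes cost effect switched off, so the
# closed-form truth record is exact.
config_no_diabetes_effect <- function(...) {
  simulation_config(
    diabetes_model = list(intercept = -7.3, per_unit_bmi = 0.13,
                          effect = c(consult = 0, rx_diabetes = 0,
                                     rx_other = 0, test = 0)),
    ...
  )
}

# Small merged analysis table for engine-level tests.
small_analysis_table <- function(n_women = 600, years = 3, seed = 42, ...) {
  cfg <- simulation_config(n_women = n_women, years = years, seed = seed, ...)
  cohort <- generate_cohort(cfg)
  panel <- generate_panel(cohort, cfg)
  analysis_table(cohort, panel)
}

short_adjusters <- function() {
  c("age_band", "deprivation_third", "smoking", "year_index",
    "fraction_observed")
}
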