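# Model-based standardization (g-computation): annual rates and costs per
# BMI band averaged over the covariate distribution of the fitted
# person-years, with exposure set to each band in turn and follow-up
# fraction set to 1.

# Design matrices for counterfactual exposure assignment: one per fine
# band, rows = the fitted person-years.
standardization_matrices <- function(fit) {
  design <- fit$design
  if (!identical(design$spec$exposure, "bmi_category_fine")) {
    stop("standardization requires exposure 'bmi_category_fine'", call. = FALSE)
  }
  levels_k <- design$xlev$bmi_category_fine
  tt <- stats::delete.response(design$terms)
  lapply(stats::setNames(levels_k, levels_k), function(k) {
    nd <- design$data
    nd$bmi_category_fine <- factor(k, levels = levels_k)
    if ("fraction_observed" %in% all.vars(tt)) nd$fraction_observed <- 1
    mf <- stats::model.frame(tt, nd, xlev = design$xlev,
                             na.action = stats::na.fail)
    stats::model.matrix(tt, mf)
  })
}

#' Standardized annual mean for one BMI band
#'
#' Every fitted person-year keeps its covariates, the BMI band is set to
#' `k` and the follow-up fraction to 1; the standardized mean is the
#' average predicted annual mean over all person-years.
#'
#' @param fit a categorical [fit_quasipoisson()] result
#' @param k a fine BMI band label
#' @return scalar standardized annual mean
#' @export
standardize_category <- function(fit, k) {
  levels_k <- fit$design$xlev$bmi_category_fine
  if (!k %in% levels_k) {
    stop("unknown BMI band '", k, "'", call. = FALSE)
  }
  X <- standardization_matrices(fit)[[k]]
  mean(exp(X %*% fit$beta))
}

#' Standardized annual means for all BMI bands
#'
#' @param fit a categorical [fit_quasipoisson()] result
#' @return named vector of standardized annual means, in band order
#' @export
standardize_all <- function(fit) {
  Xs <- standardization_matrices(fit)
  out <- vapply(Xs, function(X) mean(exp(X %*% fit$beta)), numeric(1))
  out[intersect(fine_bmi_levels(), names(out))]
}

# K x n_draws matrix of standardized means under parameter simulation:
# beta* ~ MVN(beta_hat, cov), standardized means recomputed per draw.
standardized_draws <- function(fit, n_draws, seed, cov = fit$cov_cluster,
                               chunk = 50L) {
  stopifnot(n_draws >= 1)
  Xs <- standardization_matrices(fit)
  Xs <- Xs[intersect(fine_bmi_levels(), names(Xs))]
  K <- length(Xs)
  n_rows <- nrow(Xs[[1]])
  Xall <- do.call(rbind, Xs)
  grp <- rep(seq_len(K), each = n_rows)
  draws <- mvn_draws(fit$beta, cov, n_draws, seed = seed)   # n_draws x p
  out <- matrix(NA_real_, K, n_draws,
                dimnames = list(names(Xs), NULL))
  for (start in seq(1, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_draws)
    E <- exp(Xall %*% t(draws[idx, , drop = FALSE]))
    out[, idx] <- rowsum(E, grp, reorder = TRUE) / n_rows
  }
  out
}

#' Standardized estimates with parameter-simulation 99% CIs
#'
#' Coefficients are drawn `n_draws` times from a multivariate normal with
#' the cluster-robust covariance; the standardized means are recomputed
#' per draw and the CI taken as the 0.5 and 99.5 percentiles (bootstrap
#' percentile method). A covariance with small negative eigenvalues is
#' repaired by flooring them at zero.
#'
#' @param fit a categorical [fit_quasipoisson()] result
#' @param n_draws number of parameter draws (>= 100; default 10000)
#' @param seed seed for the draw stream
#' @return object of class `standardized_estimates`: data.frame with
#'   `category`, `estimate`, `ci_low`, `ci_high`
#' @export
standardized_cis <- function(fit, n_draws = 10000, seed = 1) {
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  est <- standardize_all(fit)
  d <- standardized_draws(fit, n_draws, seed)
  qs <- t(apply(d, 1, stats::quantile, probs = c(0.005, 0.995), names = FALSE))
  out <- data.frame(category = names(est), estimate = as.numeric(est),
                    ci_low = qs[, 1], ci_high = qs[, 2], row.names = NULL)
  class(out) <- c("standardized_estimates", "data.frame")
  out
}
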