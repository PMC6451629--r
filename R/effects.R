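# Reported effect measures: percentage differences across BMI bands with
# floated (quasi-variance) group-specific 99% CIs, the linear trend per
# 2 kg/m2 above 20, measured-BMI remapping, and subgroup heterogeneity.

#' Floated (quasi-)variances for category effects
#'
#' Assigns a pseudo-variance to every exposure category, including the
#' reference, such that the variance of any pairwise contrast is
#' approximated by the sum of the two category variances. The quasi-
#' variances minimize the squared error of log contrast variances
#' `sum_{i<j} (log(v_i + v_j) - log Var(lambda_i - lambda_j))^2` over all
#' pairs (reference pairs contribute `Var(lambda_j)`), solved by
#' deterministic gradient-based least squares on the log scale. Group-
#' specific 99% CIs are `exp(lambda_k +/- 2.5758 sqrt(v_k))`.
#'
#' @param contrast_cov covariance matrix of the K-1 non-reference log
#'   relative risks (cluster-robust in intended use)
#' @param lambda named log relative risks for the non-reference categories
#'   (default 0s, if only variances are wanted)
#' @param reference label for the reference category
#' @return object of class `floated_effects`: data.frame with columns
#'   `category`, `lambda`, `floated_var`, `percent_diff`, `ci_low`,
#'   `ci_high` (CIs on the percent scale); the maximum relative error of
#'   the pairwise-variance approximation is attached as attribute
#'   `max_relative_error`.
#' @export
floated_variances <- function(contrast_cov,
                              lambda = stats::setNames(rep(0, ncol(contrast_cov)),
                                                       colnames(contrast_cov)),
                              reference = "reference") {
  V <- as.matrix(contrast_cov)
  m <- ncol(V)
  K <- m + 1
  if (K < 3) stop("quasi-variances need at least 3 categories", call. = FALSE)
  if (length(lambda) != m) {
    stop("lambda must have one entry per non-reference category", call. = FALSE)
  }
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("contrast covariance is not positive semi-definite", call. = FALSE)
  }
  # pairwise contrast variances; index 1 is the reference
  D <- matrix(0, K, K)
  D[1, -1] <- diag(V)
  D[-1, 1] <- diag(V)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) D[i + 1, j + 1] <- V[i, i] + V[j, j] - 2 * V[i, j]
    }
  }
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]
  if (any(d <= 0)) {
    stop("degenerate contrast covariance: a pairwise contrast has zero variance",
         call. = FALSE)
  }
  logd <- log(d)
  obj <- function(w) {
    v <- exp(w)
    r <- log(v[pairs[, 1]] + v[pairs[, 2]]) - logd
    sum(r^2)
  }
  grad <- function(w) {
    v <- exp(w)
    s <- v[pairs[, 1]] + v[pairs[, 2]]
    r <- log(s) - logd
    g <- numeric(K)
    contrib1 <- 2 * r * v[pairs[, 1]] / s
    contrib2 <- 2 * r * v[pairs[, 2]] / s
    for (k in seq_len(K)) {
      g[k] <- sum(contrib1[pairs[, 1] == k]) + sum(contrib2[pairs[, 2] == k])
    }
    g
  }
  # deterministic multi-start: (i) linear least squares of v_i + v_j = D_ij
  # on the raw scale, (ii) the shared-reference structure, (iii) flat; all
  # floored away from zero, where the log-scale gradient vanishes
  floor_v <- 1e-6 * mean(diag(V))
  A <- matrix(0, nrow(pairs), K)
  A[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  A[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  v_ls <- tryCatch(as.numeric(qr.solve(crossprod(A), crossprod(A, d))),
                   error = function(e) rep(mean(d) / 2, K))
  v0 <- max(mean(V[upper.tri(V)]), floor_v)
  starts <- list(pmax(v_ls, floor_v),
                 pmax(c(v0, diag(V) - v0), floor_v),
                 rep(mean(d) / 2, K))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(log(s), obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  v <- exp(best$par)
  approx_err <- max(abs((v[pairs[, 1]] + v[pairs[, 2]]) / d - 1))
  lam <- c(0, as.numeric(lambda))
  cats <- c(reference, names(lambda) %||% paste0("cat", seq_len(m)))
  z <- z99()
  out <- data.frame(category = cats, lambda = lam, floated_var = v,
                    percent_diff = 100 * (exp(lam) - 1),
                    ci_low = 100 * (exp(lam - z * sqrt(v)) - 1),
                    ci_high = 100 * (exp(lam + z * sqrt(v)) - 1),
                    row.names = NULL)
  attr(out, "max_relative_error") <- approx_err
  class(out) <- c("floated_effects", "data.frame")
  out
}

#' Percentage differences across BMI bands with floated 99% CIs
#'
#' Extracts the fine-band log effects and their cluster-robust contrast
#' covariance from a categorical fit and delegates to
#' [floated_variances()]. Rows are returned in BMI band order with the
#' reference (20 to <22.5) at 0%.
#'
#' @param fit a [fit_quasipoisson()] result whose exposure is
#'   `bmi_category_fine`
#' @return a `floated_effects` data.frame in band order
#' @export
percent_differences <- function(fit) {
  spec <- fit$design$spec
  if (!identical(spec$exposure, "bmi_category_fine")) {
    stop("percent_differences requires exposure 'bmi_category_fine'",
         call. = FALSE)
  }
  idx <- grep("^bmi_category_fine", names(fit$beta))
  if (!length(idx)) stop("no BMI category coefficients in fit", call. = FALSE)
  lam <- fit$beta[idx]
  names(lam) <- sub("^bmi_category_fine", "", names(lam))
  V <- fit$cov_cluster[idx, idx, drop = FALSE]
  eff <- floated_variances(V, lambda = lam, reference = reference_fine_level())
  ord <- match(intersect(fine_bmi_levels(), eff$category), eff$category)
  eff <- eff[ord, , drop = FALSE]
  rownames(eff) <- NULL
  class(eff) <- c("floated_effects", "data.frame")
  eff
}

#' Linear trend per 2 kg/m2 higher BMI above 20
#'
#' Restricts to rows with BMI > 20 (strictly), enters BMI linearly, and
#' reports the percentage difference per 2 kg/m2 with a conventional
#' cluster-robust 99% CI.
#'
#' @param data person-year analysis table
#' @param spec a [model_spec()]; its exposure is forced to
#'   `bmi_linear_above20` and the BMI > 20 restriction is added to any
#'   existing subset
#' @return object of class `trend_estimate`: list with `slope` (per
#'   1 kg/m2), `se` (cluster-robust), `pct_per_2`, `ci` and the fit
#' @export
trend_above_20 <- function(data, spec) {
  sub <- "bmi > 20"
  if (!is.null(spec$subset)) sub <- sprintf("(%s) & (%s)", spec$subset, sub)
  spec2 <- model_spec(outcome = spec$outcome, exposure = "bmi_linear_above20",
                      adjusters = spec$adjusters, subset = sub,
                      cluster = spec$cluster)
  design <- build_design(data, spec2)
  fit <- fit_quasipoisson(design)
  b <- fit$beta[["bmi"]]
  se <- sqrt(fit$cov_cluster["bmi", "bmi"])
  z <- z99()
  structure(list(slope = b, se = se,
                 pct_per_2 = 100 * (exp(2 * b) - 1),
                 ci = 100 * (exp(2 * (b + c(-1, 1) * z * se)) - 1),
                 fit = fit),
            class = "trend_estimate")
}

#' Replace self-reported BMI by mean measured BMI within bands
#'
#' Emulates the measurement-error sensitivity analysis: the continuous BMI
#' column is replaced by a supplied mean measured value per fine band
#' (band assignments themselves are unchanged).
#'
#' @param data analysis table with `bmi` and `bmi_category_fine`
#' @param mapping named numeric, fine band -> mean measured BMI
#' @return the data with `bmi` remapped
#' @export
remap_measured_bmi <- function(data, mapping) {
  cats <- as.character(unique(data$bmi_category_fine))
  unmapped <- setdiff(cats, names(mapping))
  if (length(unmapped)) {
    stop("no measured-BMI mapping for band(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  data$bmi <- as.numeric(mapping[as.character(data$bmi_category_fine)])
  data
}

#' Chi-square test of heterogeneity between subgroup slopes
#'
#' Inverse-variance-weighted test: `Q = sum w_j (b_j - b_bar)^2` with
#' `w_j = 1 / v_j`, df = J - 1.
#'
#' @param slopes numeric vector of subgroup slope estimates (log scale)
#' @param variances their (cluster-robust) variances, all positive
#' @return list with `Q`, `df`, `p_value` and the pooled slope
#' @export
subgroup_heterogeneity <- function(slopes, variances) {
  if (length(slopes) < 2 || length(slopes) != length(variances)) {
    stop("need >= 2 subgroups with matching variances", call. = FALSE)
  }
  if (any(variances <= 0)) stop("all variances must be positive", call. = FALSE)
  w <- 1 / variances
  b_bar <- sum(w * slopes) / sum(w)
  Q <- sum(w * (slopes - b_bar)^2)
  df <- length(slopes) - 1
  list(Q = Q, df = df,
       p_value = stats::pchisq(Q, df, lower.tail = FALSE),
       pooled_slope = b_bar)
}
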