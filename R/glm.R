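# Quasi-Poisson engine: log-link quasi-likelihood fits on person-year
# panels, Pearson overdispersion, and cluster-robust sandwich covariance.
# The same family is used for counts and for (non-integer) costs: the
# quasi-likelihood score equations only require y >= 0 and variance
# proportional to the mean.

#' Analysis table: join panel rows to baseline covariates
#'
#' @param cohort baseline table from [generate_cohort()] (or read in)
#' @param panel person-year table from [generate_panel()] (or read in)
#' @return person-year data.frame carrying BMI and all covariates
#' @export
analysis_table <- function(cohort, panel) {
  out <- merge(panel, cohort, by = "person_id", sort = FALSE)
  out[order(out$person_id, out$year_index), , drop = FALSE]
}

#' Model specification
#'
#' @param outcome response column (a count or a cost)
#' @param exposure `"bmi_category_fine"` (8 fine bands, reference
#'   20 to <22.5), `"bmi_linear_above20"` (BMI entered linearly, intended
#'   for rows with BMI > 20), or `"none"`
#' @param adjusters character vector of adjustment columns; categorical
#'   adjusters are reference-coded with the first sorted level as reference
#'   and `"missing"` always a non-reference level; `year_index` is treated
#'   as categorical (financial year); `fraction_observed` enters linearly
#' @param subset optional filter expression as a string, evaluated in the
#'   data (e.g. `"bmi > 20"`)
#' @param cluster column defining independence units (default `person_id`)
#' @return object of class `model_spec`
#' @export
model_spec <- function(outcome, exposure = "bmi_category_fine",
                       adjusters = character(), subset = NULL,
                       cluster = "person_id") {
  exposure <- match.arg(exposure, c("bmi_category_fine", "bmi_linear_above20", "none"))
  if (exposure %in% adjusters || (exposure == "bmi_linear_above20" && "bmi" %in% adjusters)) {
    stop("exposure and adjusters must be disjoint", call. = FALSE)
  }
  structure(list(outcome = outcome, exposure = exposure,
                 adjusters = adjusters, subset = subset, cluster = cluster),
            class = "model_spec")
}

# Coerce the columns a spec uses, consistently between fitting and
# prediction. With `xlev` supplied (prediction), factor levels are fixed
# and unseen levels are an error.
prepare_model_data <- function(data, spec, xlev = NULL) {
  vars <- c(spec$adjusters,
            switch(spec$exposure,
                   bmi_category_fine = "bmi_category_fine",
                   bmi_linear_above20 = "bmi",
                   none = NULL))
  missing_cols <- setdiff(c(vars, if (is.null(xlev)) spec$outcome), names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    x <- data[[v]]
    if (v == "bmi" || (is.numeric(x) && v == "fraction_observed")) next
    if (is.numeric(x) && v != "year_index") next
    x <- as.character(x)
    if (is.null(xlev)) {
      lev <- sort(unique(x))
      if (v == "bmi_category_fine") {
        lev <- intersect(fine_bmi_levels(), unique(x))
        if (!reference_fine_level() %in% lev) {
          stop("reference BMI band '", reference_fine_level(),
               "' absent from data", call. = FALSE)
        }
        lev <- c(reference_fine_level(), setdiff(lev, reference_fine_level()))
      } else if ("missing" %in% lev) {
        lev <- c(setdiff(lev, "missing"), "missing")
      }
    } else {
      lev <- xlev[[v]]
      unseen <- setdiff(unique(x), lev)
      if (length(unseen)) {
        stop(sprintf("unseen level(s) in '%s': %s", v,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
    }
    data[[v]] <- factor(x, levels = lev)
  }
  data
}

#' Build a design bundle for a quasi-Poisson fit
#'
#' Applies the spec's subset filter, reference-codes categorical terms
#' ("missing" is its own, never-reference level), and checks full rank.
#'
#' @param data person-year analysis table (see [analysis_table()])
#' @param spec a [model_spec()]
#' @return object of class `design_bundle`: response `y`, design matrix
#'   `X`, cluster ids, processed model data, terms and factor levels
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$cluster %in% names(data)) {
    stop("cluster column '", spec$cluster, "' not found", call. = FALSE)
  }
  if (!is.null(spec$subset)) {
    keep <- eval(parse(text = spec$subset), data, parent.frame())
    if (!is.logical(keep)) stop("subset must evaluate to logical", call. = FALSE)
    data <- data[keep & !is.na(keep), , drop = FALSE]
  }
  if (nrow(data) == 0) {
    stop("no rows left after applying subset '", spec$subset, "'", call. = FALSE)
  }
  data <- prepare_model_data(data, spec)
  y <- data[[spec$outcome]]
  if (anyNA(y) || any(!is.finite(y))) {
    stop("response '", spec$outcome, "' contains missing or non-finite values",
         call. = FALSE)
  }
  if (any(y < 0)) stop("response '", spec$outcome, "' must be non-negative",
                       call. = FALSE)
  rhs <- c(switch(spec$exposure,
                  bmi_category_fine = "bmi_category_fine",
                  bmi_linear_above20 = "bmi",
                  none = NULL),
           spec$adjusters)
  form <- stats::reformulate(if (length(rhs)) rhs else "1",
                             response = NULL, intercept = TRUE)
  mf <- stats::model.frame(form, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(form, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xlev <- lapply(Filter(is.factor, mf), levels)
  structure(list(y = as.numeric(y), X = X,
                 cluster = data[[spec$cluster]],
                 data = data, terms = stats::terms(form),
                 xlev = xlev, spec = spec),
            class = "design_bundle")
}

#' Fit a log-link quasi-Poisson model
#'
#' Iteratively reweighted least squares (relative deviance change < 1e-8,
#' at most 100 iterations), Pearson dispersion `phi = X2 / (n - p)`,
#' model-based covariance `phi * (X'WX)^-1`, and cluster-robust sandwich
#' covariance (see [cluster_robust_cov()]).
#'
#' @param design a [build_design()] bundle
#' @return object of class `qp_fit`
#' @export
fit_quasipoisson <- function(design) {
  stopifnot(inherits(design, "design_bundle"))
  y <- design$y; X <- design$X
  if (sum(y) == 0) {
    stop("all-zero response: log link has no support at mu = 0", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::quasipoisson(link = "log"),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  mu <- fit$fitted.values
  n <- length(y); p <- ncol(X)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  # working weights at the converged mu (glm.fit$weights lag one iteration)
  bread <- chol2inv(chol(crossprod(X * sqrt(mu))))
  cov_model <- phi * bread
  dimnames(cov_model) <- list(colnames(X), colnames(X))
  out <- structure(list(beta = fit$coefficients, cov_model = cov_model,
                        dispersion = phi, fitted = mu,
                        iterations = fit$iter, deviance = fit$deviance,
                        converged = fit$converged,
                        bread = bread, design = design, n = n, p = p),
                   class = "qp_fit")
  out$cov_cluster <- cluster_robust_cov(out, design)
  out
}

#' Cluster-robust sandwich covariance
#'
#' `V = B^-1 (sum_g s_g s_g') B^-1` with bread `B = X'WX`, cluster scores
#' `s_g = sum_{i in g} x_i (y_i - mu_i)` (no dispersion factor in the
#' meat), and small-sample factor `G / (G - 1)`.
#'
#' @param fit a [fit_quasipoisson()] result
#' @param design the design bundle the model was fitted on
#' @return covariance matrix of the coefficients
#' @export
cluster_robust_cov <- function(fit, design = fit$design) {
  g <- design$cluster
  G <- length(unique(g))
  if (G < 2) stop("cluster-robust covariance needs at least 2 clusters",
                  call. = FALSE)
  scores <- design$X * (design$y - fit$fitted)
  S <- rowsum(scores, group = g, reorder = FALSE)
  meat <- crossprod(as.matrix(S))
  V <- fit$bread %*% meat %*% fit$bread * (G / (G - 1))
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fit$cov_model)
  V
}

#' Predicted annual means for new covariate profiles
#'
#' `mu = exp(x' beta)` per row. Unless `fraction_observed` is `NULL`, the
#' `fraction_observed` column (when part of the model) is overridden with
#' the given value so that predictions are annualized.
#'
#' @param fit a [fit_quasipoisson()] result
#' @param newdata data.frame carrying every design column
#' @param fraction_observed value imposed on the follow-up fraction
#'   (default 1 = full year); `NULL` keeps the values in `newdata`
#' @return numeric vector of predicted means
#' @export
predict_mean <- function(fit, newdata, fraction_observed = 1) {
  design <- fit$design
  if (!is.null(fraction_observed) &&
      "fraction_observed" %in% all.vars(design$terms)) {
    newdata$fraction_observed <- fraction_observed
  }
  newdata <- prepare_model_data(newdata, design$spec, xlev = design$xlev)
  tt <- stats::delete.response(design$terms)
  mf <- stats::model.frame(tt, newdata, xlev = design$xlev,
                           na.action = stats::na.fail)
  Xn <- stats::model.matrix(tt, mf)
  as.numeric(exp(Xn %*% fit$beta))
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit: %d obs, %d coefficients, dispersion %.3f\n",
              x$n, x$p, x$dispersion))
  se_m <- sqrt(diag(x$cov_model)); se_c <- sqrt(diag(x$cov_cluster))
  print(data.frame(estimate = x$beta, model_se = se_m, cluster_se = se_c))
  invisible(x)
}

#' Export a fit as a coefficient table
#'
#' @param fit a `qp_fit`
#' @param path optional CSV path; when given, a header block records the
#'   dispersion before the coefficient table
#' @return data.frame of term, estimate, model SE, cluster SE
#' @export
fit_to_table <- function(fit, path = NULL) {
  tab <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                    model_se = sqrt(diag(fit$cov_model)),
                    cluster_se = sqrt(diag(fit$cov_cluster)),
                    row.names = NULL)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(sprintf("# dispersion,%.8g", fit$dispersion), con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
  }
  tab
}
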