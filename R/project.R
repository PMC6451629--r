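# Projection of standardized per-person annual costs to an external
# population: total and excess-weight-attributable costs by coarse BMI
# band, with parametric-bootstrap percentile intervals, and the
# decomposition of attributable prescription costs by therapeutic use.

# Extract a named fine-band cost vector from whatever the caller has.
as_fine_costs <- function(std) {
  if (inherits(std, "standardized_estimates")) {
    stats::setNames(std$estimate, std$category)
  } else if (is.numeric(std) && !is.null(names(std))) {
    std
  } else {
    stop("std must be a standardized_estimates or a named numeric vector",
         call. = FALSE)
  }
}

# Weighted coarse per-person costs and the 20-24.9 reference cost.
coarse_costs_from_vector <- function(c_fine, population) {
  w <- population$weights
  missing_fine <- setdiff(w$fine[w$weight > 0], names(c_fine))
  if (length(missing_fine)) {
    stop("missing fine-band estimate(s): ",
         paste(missing_fine, collapse = ", "), call. = FALSE)
  }
  coarse <- vapply(coarse_bmi_levels(), function(cc) {
    wi <- w[w$coarse == cc, ]
    sum(wi$weight * c_fine[wi$fine])
  }, numeric(1))
  # reference: weighted average of the two bands spanning 20-24.9, using
  # the <25 band weights restricted to those two bands
  wref <- w[w$coarse == "<25" & w$fine %in% reference_coarse_members(), ]
  if (nrow(wref) == 0 || sum(wref$weight) <= 0) {
    stop("population weights assign no mass to the 20-24.9 reference bands",
         call. = FALSE)
  }
  reference <- sum(wref$weight * c_fine[wref$fine]) / sum(wref$weight)
  list(coarse = coarse, reference = reference)
}

#' Coarse per-person costs and the 20-24.9 reference cost
#'
#' Fine-band standardized costs are combined into the five coarse bands
#' with the population table's fine weights; the reference cost is the
#' weighted average of the 20 to <22.5 and 22.5 to <25 estimates using the
#' <25 band's weights restricted (and renormalized) to those two bands.
#'
#' @param std a [standardized_cis()] result or named fine-band cost vector
#' @param population a [generate_population_table()]
#' @return list with `coarse` (named vector) and `reference` (scalar)
#' @export
coarse_costs <- function(std, population) {
  coarse_costs_from_vector(as_fine_costs(std), population)
}

project_rows <- function(c_fine, population) {
  cc <- coarse_costs_from_vector(c_fine, population)
  n <- stats::setNames(population$counts$n_million, population$counts$coarse)
  if (any(n < 0)) stop("negative population count", call. = FALSE)
  ge25 <- setdiff(coarse_bmi_levels(), "<25")
  total <- n[coarse_bmi_levels()] * cc$coarse[coarse_bmi_levels()]
  attrib <- n[ge25] * (cc$coarse[ge25] - cc$reference)
  prop <- attrib / total[ge25]
  agg_total <- sum(total[ge25])
  agg_attrib <- sum(attrib)
  data.frame(
    category = c(coarse_bmi_levels(), ">=25"),
    n_million = c(as.numeric(n[coarse_bmi_levels()]), sum(n[ge25])),
    per_person_cost = c(as.numeric(cc$coarse[coarse_bmi_levels()]),
                        agg_total / sum(n[ge25])),
    total_cost_m = c(as.numeric(total), agg_total),
    attributable_m = c(NA, as.numeric(attrib), agg_attrib),
    attributable_prop = c(NA, as.numeric(prop), agg_attrib / agg_total),
    reference_cost = cc$reference,
    row.names = NULL
  )
}

#' Project annual costs to the external population
#'
#' Per coarse band: total annual cost `T_k = N_k c_k`, excess-weight-
#' attributable cost `A_k = N_k (c_k - c_ref)`, attributable proportion
#' `P_k = A_k / T_k`, plus the >=25 aggregate (sums of the band rows).
#' Costs are in GBP millions when populations are in millions of women and
#' per-person costs in GBP. Negative attributable costs are retained.
#'
#' @inheritParams coarse_costs
#' @return object of class `projection_result`: data.frame with one row
#'   per coarse band plus the `>=25` aggregate; `attributable_pct` holds
#'   the proportion as a percentage rounded half away from zero.
#' @export
project_costs <- function(std, population) {
  out <- project_rows(as_fine_costs(std), population)
  out$attributable_pct <- round_half_up(100 * out$attributable_prop)
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Projection with bootstrap percentile 99% CIs
#'
#' Model parameters are simulated `n_draws` times from the cluster-robust
#' covariance; standardization and projection are recomputed per draw;
#' CIs for attributable costs and proportions are the 0.5 and 99.5
#' percentiles. Population counts are treated as fixed.
#'
#' @param fit a categorical cost-model [fit_quasipoisson()] result
#' @param population a [generate_population_table()]
#' @param n_draws number of parameter draws (>= 100; default 10000)
#' @param seed seed for the draw stream
#' @return a `projection_result` with columns `attributable_ci_low/high`
#'   and `prop_ci_low/high` on the attributable rows
#' @export
bootstrap_projection <- function(fit, population, n_draws = 10000, seed = 1) {
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  point <- project_costs(standardize_all(fit), population)
  draws <- standardized_draws(fit, n_draws, seed)          # K x n_draws
  w <- population$weights
  ge25 <- setdiff(coarse_bmi_levels(), "<25")
  n <- stats::setNames(population$counts$n_million, population$counts$coarse)
  W <- sapply(coarse_bmi_levels(), function(cc) {
    wi <- w[w$coarse == cc, ]
    out <- stats::setNames(rep(0, nrow(draws)), rownames(draws))
    out[wi$fine] <- wi$weight
    out
  })                                                       # K x 5
  coarse_d <- t(W) %*% draws                               # 5 x n_draws
  wref <- w[w$coarse == "<25" & w$fine %in% reference_coarse_members(), ]
  wref_vec <- stats::setNames(rep(0, nrow(draws)), rownames(draws))
  wref_vec[wref$fine] <- wref$weight / sum(wref$weight)
  ref_d <- as.numeric(crossprod(wref_vec, draws))
  attrib_d <- (coarse_d[ge25, , drop = FALSE] -
                 rep(ref_d, each = length(ge25))) * n[ge25]
  total_d <- coarse_d[ge25, , drop = FALSE] * n[ge25]
  agg_attrib <- colSums(attrib_d)
  agg_total <- colSums(total_d)
  A <- rbind(attrib_d, `>=25` = agg_attrib)
  P <- rbind(attrib_d / total_d, `>=25` = agg_attrib / agg_total)
  qs <- function(m) t(apply(m, 1, stats::quantile, probs = c(0.005, 0.995),
                            names = FALSE))
  qa <- qs(A); qp <- qs(P)
  rows <- match(c(ge25, ">=25"), point$category)
  point$attributable_ci_low <- NA_real_
  point$attributable_ci_high <- NA_real_
  point$prop_ci_low <- NA_real_
  point$prop_ci_high <- NA_real_
  point$attributable_ci_low[rows] <- qa[, 1]
  point$attributable_ci_high[rows] <- qa[, 2]
  point$prop_ci_low[rows] <- qp[, 1]
  point$prop_ci_high[rows] <- qp[, 2]
  point
}

#' Attributable prescription costs by therapeutic use
#'
#' One cost model per therapeutic-use category: each is standardized,
#' combined to coarse bands, and its >=25 attributable cost computed
#' relative to the 20-24.9 reference; shares are relative to the summed
#' attributable cost.
#'
#' @param fits_by_use named list of categorical [fit_quasipoisson()]
#'   results, one per therapeutic-use category
#' @param population a [generate_population_table()]
#' @return data.frame `use`, `attributable_m`, `share`, ordered by
#'   decreasing attributable cost
#' @export
therapeutic_attribution <- function(fits_by_use, population) {
  if (is.null(names(fits_by_use)) || any(names(fits_by_use) == "")) {
    stop("fits_by_use must be a named list", call. = FALSE)
  }
  n <- stats::setNames(population$counts$n_million, population$counts$coarse)
  ge25 <- setdiff(coarse_bmi_levels(), "<25")
  attrib <- vapply(fits_by_use, function(fit) {
    cc <- coarse_costs_from_vector(standardize_all(fit), population)
    sum(n[ge25] * (cc$coarse[ge25] - cc$reference))
  }, numeric(1))
  out <- data.frame(use = names(attrib), attributable_m = as.numeric(attrib),
                    share = as.numeric(attrib) / sum(attrib), row.names = NULL)
  out[order(-out$attributable_m), ]
}
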