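# Synthetic cohort generator.
#
# Emulates the structure of a linked primary-care cohort of women aged
# 55-79: a baseline table (self-reported BMI and covariates), a person-year
# panel of consultation / prescription / test counts and costs with
# overdispersion and within-person correlation, a unit-cost lookup, and a
# population BMI-distribution table for projection. Every generative
# parameter is recorded so ground truth is available to tests.

#' Therapeutic-use categories for prescriptions
#'
#' Eighteen abstract categories emulating the standard BNF chapters plus
#' analgesics, drugs in diabetes, and dressings/appliances.
#' @export
rx_use_levels <- function() {
  c("gastrointestinal", "cardiovascular", "respiratory", "cns",
    "infections", "endocrine", "obstetrics_gynae_urinary",
    "malignant_disease", "nutrition_blood", "musculoskeletal", "eye",
    "ear_nose_throat", "skin", "immunological", "anaesthesia",
    "analgesics", "diabetes_drugs", "dressings_appliances")
}

default_rx_shares <- function() {
  s <- c(gastrointestinal = 0.08, cardiovascular = 0.20, respiratory = 0.06,
         cns = 0.10, infections = 0.05, endocrine = 0.05,
         obstetrics_gynae_urinary = 0.04, malignant_disease = 0.02,
         nutrition_blood = 0.04, musculoskeletal = 0.05, eye = 0.03,
         ear_nose_throat = 0.02, skin = 0.04, immunological = 0.02,
         anaesthesia = 0.01, analgesics = 0.09, diabetes_drugs = 0.05,
         dressings_appliances = 0.05)
  s[rx_use_levels()]
}

default_unit_costs <- function() {
  rx <- c(gastrointestinal = 6.0, cardiovascular = 6.5, respiratory = 13.0,
          cns = 9.0, infections = 6.0, endocrine = 9.0,
          obstetrics_gynae_urinary = 9.0, malignant_disease = 35.0,
          nutrition_blood = 7.0, musculoskeletal = 6.0, eye = 7.0,
          ear_nose_throat = 6.0, skin = 7.0, immunological = 12.0,
          anaesthesia = 8.0, analgesics = 5.5, diabetes_drugs = 12.0,
          dressings_appliances = 8.0)
  c(consultation = 41.1, test = 7.0, rx[rx_use_levels()])
}

# Centre log effects so each covariate's population-mean multiplier is 1:
# baseline_rate then stays the marginal mean annual count in the reference
# BMI band, not the covariate-reference cell mean.
center_effects <- function(cv) {
  cv$effects <- cv$effects - log(sum(cv$probs * exp(cv$effects)))
  cv
}

default_covariate_model <- function() {
  lapply(list(
    age_band = list(levels = c("55-59", "60-64", "65-69", "70-74", "75-79"),
                    probs = c(0.25, 0.25, 0.20, 0.17, 0.13),
                    effects = c(0, 0.08, 0.16, 0.24, 0.32)),
    region = list(levels = c("north", "midlands", "london", "south"),
                  probs = c(0.30, 0.25, 0.15, 0.30),
                  effects = c(0, 0.01, -0.02, 0.00)),
    deprivation_third = list(levels = c("least", "middle", "most"),
                             probs = c(0.36, 0.33, 0.31),
                             effects = c(0, 0.03, 0.07)),
    education = list(levels = c("none", "secondary", "tertiary"),
                     probs = c(0.42, 0.44, 0.14),
                     effects = c(0, -0.02, -0.05)),
    smoking = list(levels = c("never", "former", "current"),
                   probs = c(0.52, 0.29, 0.19),
                   effects = c(0, 0.05, 0.12)),
    alcohol = list(levels = c("drinker", "non-drinker"),
                   probs = c(0.78, 0.22),
                   effects = c(0, 0.04)),
    parity = list(levels = c("0", "1-2", "3+"),
                  probs = c(0.12, 0.58, 0.30),
                  effects = c(0, 0.01, 0.03)),
    age_first_birth = list(levels = c("<22", "22-25", ">25"),
                           probs = c(0.30, 0.40, 0.30),
                           effects = c(0.02, 0, 0.01))
  ), center_effects)
}

#' Simulation configuration
#'
#' Assembles the full set of generative parameters with defaults calibrated
#' to the study conditions the pipeline is meant to emulate: a BMI
#' distribution of women aged 55-79 with 47% below 25 kg/m2, log-linear
#' BMI-rate relationships above 20 kg/m2 (flat below)
#' whose implied cost trends per 2 kg/m2 are +5.2% (consultations) and
#' +9.9% (prescriptions) with no test-cost trend, reference annual means of
#' 7.0 consultations / 27.0 prescription items / 8.0 tests, negative-binomial
#' overdispersion (target Pearson dispersion 1.5) plus a log-normal person
#' frailty creating within-person correlation, partial-year follow-up via an
#' annual dropout hazard, and a BMI-dependent diabetes hazard whose flag is
#' carried forward and multiplies prescription means (concentrated on the
#' drugs-in-diabetes category).
#'
#' @param n_women number of women in the cohort
#' @param years maximum follow-up years
#' @param seed master seed; all generator streams derive from it
#' @param bmi_mix two-component normal mixture for BMI, truncated at 18.5:
#'   list with `weight`, `mean1`, `sd1`, `mean2`, `sd2`
#' @param baseline_rate named (consult, rx, test) mean annual counts in the
#'   reference band (20 to <22.5)
#' @param slope_per_unit_bmi named (consult, rx, test) log-rate increase per
#'   1 kg/m2 above 20 (the relationship is flat below 20)
#' @param dispersion named (consult, rx, test) negative-binomial
#'   overdispersion target (variance = dispersion * mean), >= 1
#' @param frailty_sd sd of the person-level log-normal frailty
#' @param covariate_model per-covariate levels, sampling probabilities and
#'   log-scale effects; the defaults are centred so each covariate's
#'   population-mean multiplier is 1 and `baseline_rate` keeps its marginal
#'   interpretation
#' @param dropout_rate annual probability that follow-up ends mid-year
#' @param diabetes_model list: `intercept` and `per_unit_bmi` of the annual
#'   log-odds of incident diabetes, and multiplicative `effect` (log scale)
#'   of prevalent diabetes, named (consult, rx_diabetes, rx_other, test)
#' @param missing_covariate_prob per-covariate probability of a "missing"
#'   label
#' @param rx_use_shares shares of prescription items across the 18
#'   therapeutic-use categories (sum to 1)
#' @param underweight_rx_excess optional log-scale excess prescription
#'   mean in the 18.5 to <20 band (default 0: not part of the core model)
#' @param unit_costs named unit costs (GBP, 2016 prices) for
#'   "consultation", "test" and each therapeutic-use category
#' @return object of class `sim_config`
#' @export
simulation_config <- function(n_women = 5000,
                              years = 6,
                              seed = 1,
                              bmi_mix = list(weight = 0.637, mean1 = 24.59,
                                             sd1 = 3.95, mean2 = 23.52,
                                             sd2 = 9.55),
                              baseline_rate = c(consult = 7.0, rx = 27.0, test = 8.0),
                              slope_per_unit_bmi = c(consult = log(1.052) / 2,
                                                     rx = log(1.099) / 2,
                                                     test = 0),
                              dispersion = c(consult = 1.5, rx = 1.5, test = 1.5),
                              frailty_sd = 0.25,
                              covariate_model = default_covariate_model(),
                              dropout_rate = 0.05,
                              diabetes_model = list(intercept = -7.3,
                                                    per_unit_bmi = 0.13,
                                                    effect = c(consult = 0.10,
                                                               rx_diabetes = 2.2,
                                                               rx_other = 0.10,
                                                               test = 0)),
                              missing_covariate_prob = 0.02,
                              rx_use_shares = default_rx_shares(),
                              underweight_rx_excess = 0,
                              unit_costs = default_unit_costs()) {
  config <- list(n_women = n_women, years = years, seed = seed,
                 bmi_mix = bmi_mix, baseline_rate = baseline_rate,
                 slope_per_unit_bmi = slope_per_unit_bmi,
                 dispersion = dispersion, frailty_sd = frailty_sd,
                 covariate_model = covariate_model,
                 dropout_rate = dropout_rate, diabetes_model = diabetes_model,
                 missing_covariate_prob = missing_covariate_prob,
                 rx_use_shares = rx_use_shares,
                 underweight_rx_excess = underweight_rx_excess,
                 unit_costs = unit_costs)
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  cfg_stop <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(config$n_women) || config$n_women < 1) {
    cfg_stop("n_women", "must be >= 1")
  }
  if (!is.numeric(config$years) || config$years < 1) {
    cfg_stop("years", "must be >= 1")
  }
  bm <- config$bmi_mix
  need <- c("weight", "mean1", "sd1", "mean2", "sd2")
  if (!all(need %in% names(bm))) cfg_stop("bmi_mix", "must name weight/mean1/sd1/mean2/sd2")
  if (bm$weight < 0 || bm$weight > 1) cfg_stop("bmi_mix", "weight must be in [0,1]")
  if (bm$sd1 <= 0 || bm$sd2 <= 0) cfg_stop("bmi_mix", "sds must be positive")
  for (f in c("baseline_rate")) {
    if (any(config[[f]] <= 0)) cfg_stop(f, "entries must be positive")
  }
  if (any(config$dispersion < 1)) cfg_stop("dispersion", "must be >= 1")
  if (config$frailty_sd < 0) cfg_stop("frailty_sd", "must be >= 0")
  for (f in c("dropout_rate", "missing_covariate_prob")) {
    if (config[[f]] < 0 || config[[f]] > 1) cfg_stop(f, "must be in [0,1]")
  }
  shares <- config$rx_use_shares
  if (!setequal(names(shares), rx_use_levels())) {
    cfg_stop("rx_use_shares", "must cover the 18 therapeutic-use categories")
  }
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-8) {
    cfg_stop("rx_use_shares", "must be non-negative and sum to 1")
  }
  uc <- config$unit_costs
  if (!all(c("consultation", "test", rx_use_levels()) %in% names(uc))) {
    cfg_stop("unit_costs", "must name consultation, test and all therapeutic uses")
  }
  if (any(uc < 0)) cfg_stop("unit_costs", "must be non-negative")
  for (cv in names(config$covariate_model)) {
    cm <- config$covariate_model[[cv]]
    if (length(cm$levels) != length(cm$probs) ||
        length(cm$levels) != length(cm$effects)) {
      cfg_stop(paste0("covariate_model$", cv),
               "levels, probs and effects must have equal length")
    }
    if (any(cm$probs < 0) || abs(sum(cm$probs) - 1) > 1e-8) {
      cfg_stop(paste0("covariate_model$", cv), "probs must sum to 1")
    }
  }
  invisible(config)
}

# Draw from the truncated two-normal BMI mixture by rejection.
draw_bmi <- function(n, bmi_mix, lower = 18.5) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 64L)
    comp <- stats::runif(m) < bmi_mix$weight
    x <- ifelse(comp,
                stats::rnorm(m, bmi_mix$mean1, bmi_mix$sd1),
                stats::rnorm(m, bmi_mix$mean2, bmi_mix$sd2))
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Generate a baseline cohort table
#'
#' Draws BMI from the configured truncated mixture, covariates
#' independently from their configured category probabilities (with missing
#' values injected as the label `"missing"`), and a BMI-dependent incident
#' diabetes onset year (annual logistic hazard, first success within
#' follow-up; `NA` if none).
#'
#' @param config a [simulation_config()]
#' @return data.frame with one row per woman: `person_id`, `bmi`,
#'   `bmi_category_fine`, the eight covariates, `diabetes_onset_year`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "cohort"))
  n <- as.integer(config$n_women)
  bmi <- draw_bmi(n, config$bmi_mix)
  cohort <- data.frame(person_id = seq_len(n), bmi = bmi,
                       bmi_category_fine = bmi_fine_category(bmi),
                       stringsAsFactors = FALSE)
  for (cv in names(config$covariate_model)) {
    cm <- config$covariate_model[[cv]]
    x <- sample(cm$levels, n, replace = TRUE, prob = cm$probs)
    if (config$missing_covariate_prob > 0) {
      x[stats::runif(n) < config$missing_covariate_prob] <- "missing"
    }
    cohort[[cv]] <- x
  }
  dm <- config$diabetes_model
  p_onset <- stats::plogis(dm$intercept + dm$per_unit_bmi * bmi)
  onset <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (t in seq_len(config$years)) {
    hit <- alive & (stats::runif(n) < p_onset)
    onset[hit] <- t
    alive <- alive & !hit
  }
  cohort$diabetes_onset_year <- onset
  attr(cohort, "sim_seed") <- config$seed
  cohort
}

# log-scale covariate contribution per person; "missing" contributes 0
covariate_lp <- function(cohort, covariate_model) {
  lp <- numeric(nrow(cohort))
  for (cv in names(covariate_model)) {
    cm <- covariate_model[[cv]]
    eff <- stats::setNames(cm$effects, cm$levels)
    contrib <- eff[cohort[[cv]]]
    contrib[is.na(contrib)] <- 0      # "missing" label
    lp <- lp + as.numeric(contrib)
  }
  lp
}

nb_draw <- function(n, mu, phi) {
  if (phi <= 1 + 1e-12) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (phi - 1))
  }
}

#' Generate a person-year panel from a cohort
#'
#' One row per woman per financial year until dropout. Counts are
#' negative-binomial realizations with mean
#' `fraction_observed * baseline * exp(slope * max(bmi - 20, 0) +
#' covariate effects + frailty + diabetes effect)` and configured
#' overdispersion; costs equal counts times unit costs exactly; the
#' diabetes flag turns on in the onset year and is carried forward.
#'
#' @param cohort output of [generate_cohort()] under the same config
#' @param config the same [simulation_config()]
#' @return data.frame person-year panel (wide therapeutic-use columns
#'   `rx_count_*`, `rx_cost_*`).
#' @export
generate_panel <- function(cohort, config) {
  validate_sim_config(config)
  if (nrow(cohort) != config$n_women ||
      !is.null(attr(cohort, "sim_seed")) &&
      !identical(attr(cohort, "sim_seed"), config$seed)) {
    stop("cohort/config mismatch: cohort was not generated under this config",
         call. = FALSE)
  }
  set.seed(substream_seed(config$seed, "panel"))
  n <- nrow(cohort)
  years <- as.integer(config$years)

  # follow-up: geometric dropout; the dropout year is observed partially
  if (config$dropout_rate > 0) {
    drop_year <- stats::rgeom(n, config$dropout_rate) + 1L
  } else {
    drop_year <- rep(years + 1L, n)
  }
  n_years <- pmin(drop_year, years)
  partial <- drop_year <= years
  frac_last <- stats::runif(n, min = 1 / 12, max = 1)

  idx <- rep(seq_len(n), n_years)
  year_index <- sequence(n_years)
  last_row <- cumsum(n_years)
  fraction <- rep(1, length(idx))
  fraction[last_row[partial]] <- frac_last[partial]

  frailty <- stats::rnorm(n, 0, config$frailty_sd)
  cov_lp <- covariate_lp(cohort, config$covariate_model)
  bmi_excess <- pmax(cohort$bmi - bmi_slope_knee(), 0)

  onset <- cohort$diabetes_onset_year[idx]
  flag <- !is.na(onset) & year_index >= onset

  base_lp <- cov_lp[idx] + frailty[idx]
  dm_eff <- config$diabetes_model$effect
  uc <- config$unit_costs

  panel <- data.frame(person_id = cohort$person_id[idx],
                      year_index = year_index,
                      fraction_observed = fraction,
                      diabetes_flag = flag)

  draw_outcome <- function(baseline, slope, extra_lp, phi) {
    mu <- fraction * baseline *
      exp(slope * bmi_excess[idx] + base_lp + extra_lp)
    nb_draw(length(mu), mu, phi)
  }

  panel$consult_count <- draw_outcome(config$baseline_rate[["consult"]],
                                      config$slope_per_unit_bmi[["consult"]],
                                      dm_eff[["consult"]] * flag,
                                      config$dispersion[["consult"]])
  panel$consult_cost <- panel$consult_count * uc[["consultation"]]
  panel$test_count <- draw_outcome(config$baseline_rate[["test"]],
                                   config$slope_per_unit_bmi[["test"]],
                                   dm_eff[["test"]] * flag,
                                   config$dispersion[["test"]])
  panel$test_cost <- panel$test_count * uc[["test"]]

  uw <- config$underweight_rx_excess * (cohort$bmi[idx] < 20)
  for (use in rx_use_levels()) {
    de <- if (use == "diabetes_drugs") dm_eff[["rx_diabetes"]] else dm_eff[["rx_other"]]
    cnt <- draw_outcome(config$baseline_rate[["rx"]] * config$rx_use_shares[[use]],
                        config$slope_per_unit_bmi[["rx"]],
                        de * flag + uw,
                        config$dispersion[["rx"]])
    panel[[paste0("rx_count_", use)]] <- cnt
    panel[[paste0("rx_cost_", use)]] <- cnt * uc[[use]]
  }
  panel$rx_count <- rowSums(panel[paste0("rx_count_", rx_use_levels())])
  panel$rx_cost <- rowSums(panel[paste0("rx_cost_", rx_use_levels())])
  attr(panel, "sim_seed") <- config$seed
  panel
}

#' Unit-cost lookup table
#'
#' @param config a [simulation_config()]
#' @return data.frame with columns `category`, `unit_cost` (GBP, 2016
#'   prices) covering consultations, tests and the 18 therapeutic uses.
#' @export
generate_unit_costs <- function(config = simulation_config()) {
  uc <- config$unit_costs
  data.frame(category = names(uc), unit_cost = as.numeric(uc),
             stringsAsFactors = FALSE)
}

#' Population BMI-distribution table for projection
#'
#' The default fixture reproduces the mid-2013 population of women aged
#' 55-79 in England by coarse self-reported BMI band: 2.83, 2.28, 1.06,
#' 0.30 and 0.16 million women for <25, 25-29.9, 30-34.9, 35-39.9 and >=40
#' (6.63 million in total). `fine_weights` allocate each coarse band across
#' the fine bands it contains and default to equal weights (the survey
#' weights behind the published projection are configurable inputs, never
#' hard-coded).
#'
#' @param n_million named numeric: women (millions) per coarse band
#' @param fine_weights optional data.frame (`coarse`, `fine`, `weight`);
#'   weights must sum to 1 within each coarse band
#' @return object of class `population_table`: list with elements `counts`
#'   (data.frame `coarse`, `n_million`) and `weights`
#' @export
generate_population_table <- function(n_million = c("<25" = 2.83,
                                                    "25-29.9" = 2.28,
                                                    "30-34.9" = 1.06,
                                                    "35-39.9" = 0.30,
                                                    ">=40" = 0.16),
                                      fine_weights = NULL) {
  if (!setequal(names(n_million), coarse_bmi_levels())) {
    stop("n_million must name the five coarse BMI bands", call. = FALSE)
  }
  if (any(n_million <= 0)) stop("population counts must be positive", call. = FALSE)
  map <- fine_to_coarse_map()
  if (is.null(fine_weights)) {
    fine_weights <- do.call(rbind, lapply(coarse_bmi_levels(), function(cc) {
      fines <- map$fine[map$coarse == cc]
      data.frame(coarse = cc, fine = fines, weight = 1 / length(fines),
                 stringsAsFactors = FALSE)
    }))
  }
  validate_fine_weights(fine_weights)
  counts <- data.frame(coarse = coarse_bmi_levels(),
                       n_million = as.numeric(n_million[coarse_bmi_levels()]),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, weights = fine_weights),
            class = "population_table")
}

validate_fine_weights <- function(fine_weights) {
  need <- c("coarse", "fine", "weight")
  if (!all(need %in% names(fine_weights))) {
    stop("fine_weights must have columns coarse, fine, weight", call. = FALSE)
  }
  map <- fine_to_coarse_map()
  for (cc in unique(fine_weights$coarse)) {
    w <- fine_weights$weight[fine_weights$coarse == cc]
    if (abs(sum(w) - 1) > 1e-6) {
      stop(sprintf("fine_weights for coarse band '%s' sum to %.4f, not 1",
                   cc, sum(w)), call. = FALSE)
    }
    fines <- fine_weights$fine[fine_weights$coarse == cc]
    if (!all(fines %in% map$fine[map$coarse == cc])) {
      stop(sprintf("fine_weights assign fine bands outside coarse band '%s'", cc),
           call. = FALSE)
    }
  }
  invisible(fine_weights)
}

# --- ground truth -----------------------------------------------------------

# truncated-mixture density and band probabilities
bmi_density <- function(x, bmi_mix, lower = 18.5) {
  z <- bmi_mix$weight * (1 - stats::pnorm(lower, bmi_mix$mean1, bmi_mix$sd1)) +
    (1 - bmi_mix$weight) * (1 - stats::pnorm(lower, bmi_mix$mean2, bmi_mix$sd2))
  d <- bmi_mix$weight * stats::dnorm(x, bmi_mix$mean1, bmi_mix$sd1) +
    (1 - bmi_mix$weight) * stats::dnorm(x, bmi_mix$mean2, bmi_mix$sd2)
  ifelse(x < lower, 0, d / z)
}

bmi_cdf <- function(q, bmi_mix, lower = 18.5) {
  z <- bmi_mix$weight * (1 - stats::pnorm(lower, bmi_mix$mean1, bmi_mix$sd1)) +
    (1 - bmi_mix$weight) * (1 - stats::pnorm(lower, bmi_mix$mean2, bmi_mix$sd2))
  num <- bmi_mix$weight *
    (stats::pnorm(q, bmi_mix$mean1, bmi_mix$sd1) -
       stats::pnorm(lower, bmi_mix$mean1, bmi_mix$sd1)) +
    (1 - bmi_mix$weight) *
    (stats::pnorm(q, bmi_mix$mean2, bmi_mix$sd2) -
       stats::pnorm(lower, bmi_mix$mean2, bmi_mix$sd2))
  pmax(num, 0) / z
}

# expected fraction of follow-up years with the diabetes flag on, given bmi
expected_flag_fraction <- function(bmi, diabetes_model, years) {
  p <- stats::plogis(diabetes_model$intercept + diabetes_model$per_unit_bmi * bmi)
  sapply(p, function(pp) mean(1 - (1 - pp)^seq_len(years)))
}

# E[exp(slope*(B-20)+) * diabetes factor | B in fine band k]
band_mean_factor <- function(k, slope, diab_mult, config) {
  breaks <- fine_bmi_breaks()
  i <- match(k, fine_bmi_levels())
  lo <- breaks[i]; hi <- min(breaks[i + 1], 80)
  f <- function(x) {
    g <- expected_flag_fraction(x, config$diabetes_model, config$years)
    bmi_density(x, config$bmi_mix) *
      exp(slope * pmax(x - bmi_slope_knee(), 0)) *
      (1 + (exp(diab_mult) - 1) * g)
  }
  num <- stats::integrate(f, lo, hi, rel.tol = 1e-9)$value
  den <- bmi_cdf(hi, config$bmi_mix) - bmi_cdf(lo, config$bmi_mix)
  num / den
}

# multiplicative constant shared by all bands: frailty and covariate mix
shared_mean_factor <- function(config) {
  fr <- exp(config$frailty_sd^2 / 2)
  covf <- 1
  pm <- config$missing_covariate_prob
  for (cv in names(config$covariate_model)) {
    cm <- config$covariate_model[[cv]]
    covf <- covf * ((1 - pm) * sum(cm$probs * exp(cm$effects)) + pm)
  }
  fr * covf
}

#' Ground-truth record for a simulation configuration
#'
#' Closed-form (quadrature) quantities implied by the generative model:
#' the analytic share of BMI < 25, true percent differences per 2 kg/m2,
#' true standardized annual means per fine band for each outcome (counts
#' and costs, at full-year follow-up), and the true excess-weight
#' attributable cost proportion under a given population table.
#'
#' @param config a [simulation_config()]
#' @param population a [generate_population_table()] (default fixture)
#' @return list of ground-truth quantities
#' @export
truth_record <- function(config, population = generate_population_table()) {
  validate_sim_config(config)
  shared <- shared_mean_factor(config)
  dm <- config$diabetes_model$effect
  uc <- config$unit_costs

  band_means <- function(outcome) {
    slope <- config$slope_per_unit_bmi[[outcome]]
    base <- config$baseline_rate[[outcome]]
    if (outcome == "rx") {
      sapply(fine_bmi_levels(), function(k) {
        cnt <- 0; cost <- 0
        for (use in rx_use_levels()) {
          de <- if (use == "diabetes_drugs") dm[["rx_diabetes"]] else dm[["rx_other"]]
          m <- base * config$rx_use_shares[[use]] *
            band_mean_factor(k, slope, de, config) * shared
          if (k == "18.5 to <20") m <- m * exp(config$underweight_rx_excess)
          cnt <- cnt + m
          cost <- cost + m * uc[[use]]
        }
        c(count = cnt, cost = cost)
      })
    } else {
      de <- dm[[outcome]]
      ucost <- uc[[if (outcome == "consult") "consultation" else "test"]]
      sapply(fine_bmi_levels(), function(k) {
        m <- base * band_mean_factor(k, slope, de, config) * shared
        c(count = m, cost = m * ucost)
      })
    }
  }
  means <- lapply(c(consult = "consult", rx = "rx", test = "test"), band_means)

  attr_prop <- function(costs) {
    cc <- coarse_costs_from_vector(costs, population)
    ge25 <- setdiff(coarse_bmi_levels(), "<25")
    n <- stats::setNames(population$counts$n_million, population$counts$coarse)[ge25]
    sum(n * (cc$coarse[ge25] - cc$reference)) / sum(n * cc$coarse[ge25])
  }

  list(
    config = unclass(config),
    share_bmi_lt25 = bmi_cdf(25, config$bmi_mix),
    pct_per_2kgm2 = 100 * (exp(2 * config$slope_per_unit_bmi) - 1),
    standardized_count = lapply(means, function(m) m["count", ]),
    standardized_cost = lapply(means, function(m) m["cost", ]),
    attributable_proportion = list(
      consult_cost = attr_prop(means$consult["cost", ]),
      rx_cost = attr_prop(means$rx["cost", ])
    )
  )
}

#' Simulate a full study: cohort, panel, unit costs, population, truth
#'
#' @inheritParams generate_cohort
#' @param population optional [generate_population_table()]
#' @return list with elements `cohort`, `panel`, `unit_costs`,
#'   `population`, `truth`
#' @export
simulate_study <- function(config = simulation_config(),
                           population = generate_population_table()) {
  cohort <- generate_cohort(config)
  panel <- generate_panel(cohort, config)
  list(cohort = cohort, panel = panel,
       unit_costs = generate_unit_costs(config),
       population = population,
       truth = truth_record(config, population))
}

#' Write simulated tables to a directory
#'
#' Writes `cohort.csv`, `person_years.csv`, `unit_costs.csv`,
#' `population.csv` (long format: coarse band, fine band, millions of
#' women, fine weight) and `truth.json`.
#'
#' @param sim output of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(sim$panel, file.path(dir, "person_years.csv"), row.names = FALSE)
  utils::write.csv(sim$unit_costs, file.path(dir, "unit_costs.csv"), row.names = FALSE)
  pop <- merge(sim$population$weights, sim$population$counts, by = "coarse")
  utils::write.csv(pop[, c("coarse", "fine", "n_million", "weight")],
                   file.path(dir, "population.csv"), row.names = FALSE)
  # named atomic vectors become JSON objects, not bare arrays
  as_named <- function(x) {
    if (is.list(x)) lapply(x, as_named)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_named(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
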