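# Synthetic-data generator: determinism, distributional calibration,
# exact cost/count bookkeeping, diabetes carry-forward.

test_that("generation is deterministic given the seed and sensitive to it", {
  cfg <- simulation_config(n_women = 300, years = 3, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  pa <- generate_panel(a, cfg)
  pb <- generate_panel(b, cfg)
  expect_identical(pa, pb)
  cfg2 <- simulation_config(n_women = 300, years = 3, seed = 2)
  expect_false(identical(generate_cohort(cfg2)$bmi, a$bmi))
})

test_that("missing labels appear at the configured rate, including zero", {
  cfg0 <- simulation_config(n_women = 800, seed = 3, missing_covariate_prob = 0)
  cohort0 <- generate_cohort(cfg0)
  covs <- names(cfg0$covariate_model)
  expect_false(any(unlist(cohort0[covs]) == "missing"))

  cfg <- simulation_config(n_women = 4000, seed = 3, missing_covariate_prob = 0.1)
  cohort <- generate_cohort(cfg)
  share <- mean(cohort$smoking == "missing")
  expect_lt(abs(share - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
})

test_that("BMI mixture reproduces the configured share below 25 kg/m2", {
  cfg <- simulation_config(n_women = 50000, seed = 5)
  truth <- truth_record(cfg)
  # the configured mixture targets the 47% share observed in older English women
  expect_lt(abs(truth$share_bmi_lt25 - 0.47), 0.01)
  cohort <- generate_cohort(cfg)
  p <- truth$share_bmi_lt25
  expect_lt(abs(mean(cohort$bmi < 25) - p), 3 * sqrt(p * (1 - p) / 50000))
  expect_true(all(cohort$bmi >= 18.5))
  expect_identical(as.character(cohort$bmi_category_fine),
                   as.character(bmi_fine_category(cohort$bmi)))
})

test_that("every cost column equals its count column times the unit cost", {
  cfg <- simulation_config(n_women = 400, years = 3, seed = 8)
  sim <- simulate_study(cfg)
  uc <- with(sim$unit_costs, setNames(unit_cost, category))
  expect_identical(sim$panel$consult_cost,
                   sim$panel$consult_count * uc[["consultation"]])
  expect_identical(sim$panel$test_cost, sim$panel$test_count * uc[["test"]])
  for (use in rx_use_levels()) {
    expect_identical(sim$panel[[paste0("rx_cost_", use)]],
                     sim$panel[[paste0("rx_count_", use)]] * uc[[use]])
  }
  expect_equal(sim$panel$rx_cost,
               rowSums(sim$panel[paste0("rx_cost_", rx_use_levels())]))
})

test_that("diabetes flag is monotone non-decreasing within person", {
  cfg <- simulation_config(n_women = 500, years = 6, seed = 9)
  sim <- simulate_study(cfg)
  by_person <- split(sim$panel$diabetes_flag[order(sim$panel$person_id,
                                                   sim$panel$year_index)],
                     sim$panel$person_id[order(sim$panel$person_id,
                                               sim$panel$year_index)])
  expect_true(all(vapply(by_person, function(f) !is.unsorted(f), logical(1))))
  # flag starts exactly at the recorded onset year
  cohort <- generate_cohort(cfg)
  merged <- merge(sim$panel, cohort[c("person_id", "diabetes_onset_year")])
  expect_identical(merged$diabetes_flag,
                   !is.na(merged$diabetes_onset_year) &
                     merged$year_index >= merged$diabetes_onset_year)
})

test_that("null-effect configuration yields flat annualized means across bands", {
  cm <- simulation_config()$covariate_model
  cm <- lapply(cm, function(x) { x$effects <- 0 * x$effects; x })
  cfg <- simulation_config(
    n_women = 4000, years = 5, seed = 10, frailty_sd = 0,
    slope_per_unit_bmi = c(consult = 0, rx = 0, test = 0),
    covariate_model = cm,
    diabetes_model = list(intercept = -7.3, per_unit_bmi = 0.13,
                          effect = c(consult = 0, rx_diabetes = 0,
                                     rx_other = 0, test = 0)))
  sim <- simulate_study(cfg)
  annual <- sim$panel$consult_count / sim$panel$fraction_observed
  cats <- merge(sim$panel, sim$cohort[c("person_id", "bmi_category_fine")])
  for (k in levels(cats$bmi_category_fine)) {
    x <- annual[cats$bmi_category_fine == k]
    if (length(x) < 50) next
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 7.0), 4 * se)
  }
})

test_that("generated band means reproduce the configured top-to-reference ratio", {
  # slope set so the >=40 band mean is about 11.1/7.0 times the reference
  slope <- log(11.1 / 7.0) / (40 - 20)
  cfg <- config_no_diabetes_effect(
    n_women = 30000, years = 3, seed = 12, frailty_sd = 0,
    slope_per_unit_bmi = c(consult = slope, rx = 0, test = 0))
  truth <- truth_record(cfg)
  sim_cohort <- generate_cohort(cfg)
  panel <- generate_panel(sim_cohort, cfg)
  d <- analysis_table(sim_cohort, panel)
  annual <- d$consult_count / d$fraction_observed
  emp <- tapply(annual, d$bmi_category_fine, mean)
  emp_ratio <- emp[[">=40"]] / emp[["20 to <22.5"]]
  true_ratio <- truth$standardized_count$consult[[">=40"]] /
    truth$standardized_count$consult[["20 to <22.5"]]
  expect_lt(abs(emp_ratio / true_ratio - 1), 0.05)
})

test_that("population table defaults to the 6.63 million fixture and validates", {
  pop <- generate_population_table()
  expect_equal(sum(pop$counts$n_million), 6.63)
  expect_equal(unname(tapply(pop$weights$weight, pop$weights$coarse, sum)),
               rep(1, 5), ignore_attr = TRUE)
  bad <- pop$weights
  bad$weight[1] <- bad$weight[1] / 2
  expect_error(generate_population_table(fine_weights = bad), "sum to")
})

test_that("configuration and pairing errors name the offending field", {
  expect_error(simulation_config(n_women = 0), "n_women")
  expect_error(simulation_config(dispersion = c(consult = 0.5, rx = 1.5, test = 1.5)),
               "dispersion")
  expect_error(simulation_config(dropout_rate = 1.5), "dropout_rate")
  bm <- list(weight = 0.5, mean1 = 24, sd1 = -1, mean2 = 29, sd2 = 4)
  expect_error(simulation_config(bmi_mix = bm), "bmi_mix")
  cfg <- simulation_config(n_women = 50, seed = 1)
  other <- generate_cohort(simulation_config(n_women = 60, seed = 1))
  expect_error(generate_panel(other, cfg), "mismatch")
})
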