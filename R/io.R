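# Configuration, validated file I/O and end-to-end orchestration. The
# analysis runs from a single YAML config (or an in-memory list of the
# same shape) and writes the report tables as CSV.

default_adjusters <- function() {
  c("age_band", "region", "deprivation_third", "education", "smoking",
    "alcohol", "parity", "age_first_birth", "year_index", "fraction_observed")
}

#' Read and validate a run configuration
#'
#' The config must contain exactly one of `simulate` (arguments to
#' [simulation_config()]) or `inputs` (paths to `cohort`, `person_years`,
#' `unit_costs`, `population` CSVs), plus optional `seed` (mandatory when
#' simulating or drawing), `n_draws`, `out_dir`, `adjusters` and `filters`
#' (any of `exclude_bmi_over`, `never_smokers`).
#'
#' @param path YAML file path, or a list with the same structure
#' @return validated config list of class `run_config`
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop("config must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  }
  if (is.null(config$seed)) {
    stop("config field 'seed' is mandatory", call. = FALSE)
  }
  config$n_draws <- config$n_draws %||% 1000
  config$adjusters <- config$adjusters %||% default_adjusters()
  config$out_dir <- config$out_dir %||% "results"
  class(config) <- "run_config"
  config
}

check_nonneg <- function(x, file, column) {
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    stop(sprintf("%s: column '%s' has a negative or non-finite value at row %d",
                 file, column, bad[1]), call. = FALSE)
  }
}

#' Read and validate the four input tables
#'
#' Schema violations raise an error naming the file, column and row.
#' BMI band labels are validated against the fixed category scheme, and
#' every cost column is checked to equal its count column times the unit
#' cost.
#'
#' @param paths named list/vector: `cohort`, `person_years`, `unit_costs`,
#'   `population`
#' @return list with `cohort`, `panel`, `unit_costs`, `population`
#' @export
read_tables <- function(paths) {
  need <- c("cohort", "person_years", "unit_costs", "population")
  if (!all(need %in% names(paths))) {
    stop("paths must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  cohort <- utils::read.csv(paths[["cohort"]], stringsAsFactors = FALSE)
  for (col in c("person_id", "bmi", "bmi_category_fine")) {
    if (!col %in% names(cohort)) {
      stop(sprintf("%s: missing column '%s'", paths[["cohort"]], col),
           call. = FALSE)
    }
  }
  if (any(cohort$bmi < 18.5)) {
    stop(sprintf("%s: column 'bmi' below 18.5 at row %d", paths[["cohort"]],
                 which(cohort$bmi < 18.5)[1]), call. = FALSE)
  }
  expected_cat <- as.character(bmi_fine_category(cohort$bmi))
  bad <- which(cohort$bmi_category_fine != expected_cat)
  if (length(bad)) {
    stop(sprintf("%s: column 'bmi_category_fine' inconsistent with bmi at row %d",
                 paths[["cohort"]], bad[1]), call. = FALSE)
  }

  panel <- utils::read.csv(paths[["person_years"]], stringsAsFactors = FALSE)
  for (col in c("person_id", "year_index", "fraction_observed")) {
    if (!col %in% names(panel)) {
      stop(sprintf("%s: missing column '%s'", paths[["person_years"]], col),
           call. = FALSE)
    }
  }
  if (any(panel$fraction_observed <= 0 | panel$fraction_observed > 1)) {
    stop(sprintf("%s: column 'fraction_observed' outside (0,1] at row %d",
                 paths[["person_years"]],
                 which(panel$fraction_observed <= 0 | panel$fraction_observed > 1)[1]),
         call. = FALSE)
  }
  for (col in grep("_count|_cost|^rx_count$|^rx_cost$", names(panel), value = TRUE)) {
    check_nonneg(panel[[col]], paths[["person_years"]], col)
  }
  count_cols <- grep("count", names(panel), value = TRUE)
  if (!length(count_cols)) {
    stop(sprintf("%s: no count columns found", paths[["person_years"]]),
         call. = FALSE)
  }

  uc <- utils::read.csv(paths[["unit_costs"]], stringsAsFactors = FALSE)
  if (!all(c("category", "unit_cost") %in% names(uc))) {
    stop(sprintf("%s: must have columns category, unit_cost",
                 paths[["unit_costs"]]), call. = FALSE)
  }
  if (anyDuplicated(uc$category)) {
    stop(sprintf("%s: duplicated category '%s'", paths[["unit_costs"]],
                 uc$category[duplicated(uc$category)][1]), call. = FALSE)
  }
  check_nonneg(uc$unit_cost, paths[["unit_costs"]], "unit_cost")

  pop_raw <- utils::read.csv(paths[["population"]], stringsAsFactors = FALSE)
  for (col in c("coarse", "fine", "n_million", "weight")) {
    if (!col %in% names(pop_raw)) {
      stop(sprintf("%s: missing column '%s'", paths[["population"]], col),
           call. = FALSE)
    }
  }
  n_by_coarse <- tapply(pop_raw$n_million, pop_raw$coarse, function(x) x[1])
  population <- generate_population_table(
    n_million = stats::setNames(as.numeric(n_by_coarse), names(n_by_coarse)),
    fine_weights = pop_raw[, c("coarse", "fine", "weight")]
  )
  list(cohort = cohort, panel = panel, unit_costs = uc, population = population)
}

apply_filters <- function(data, filters) {
  if (is.null(filters)) return(data)
  if (!is.null(filters$exclude_bmi_over)) {
    keep <- data$bmi <= filters$exclude_bmi_over
    if (!any(keep)) stop("filter 'exclude_bmi_over' removes all rows", call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  if (isTRUE(filters$never_smokers)) {
    keep <- data$smoking == "never"
    if (!any(keep)) stop("filter 'never_smokers' removes all rows", call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  data
}

outcome_columns <- function() {
  list(consultations = c(rate = "consult_count", cost = "consult_cost"),
       tests = c(rate = "test_count", cost = "test_cost"),
       prescriptions = c(rate = "rx_count", cost = "rx_cost"))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the study tables, fits the categorical and linear
#' quasi-Poisson models for each outcome, and writes: `table2.csv`
#' (standardized annual rates/costs per fine band with percentile CIs and
#' floated percent differences), `trends.csv` (percent difference per
#' 2 kg/m2 above 20), `table3.csv` (population projection of attributable
#' costs with bootstrap CIs), `fig2_attribution.csv` (attributable
#' prescription costs by therapeutic use), `mediation.csv` (diabetes
#' mediation for consultation and prescription costs),
#' `truth_vs_estimate.csv` (simulation mode only) and `manifest.json`.
#' Identical configs and seeds produce identical outputs.
#'
#' @param config a [read_run_config()] result (or YAML path)
#' @return the output directory, invisibly; tables are also returned as
#'   the attribute `"tables"`
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% substream_seed(config$seed, "simulation")
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_study(sim_cfg)
    tables <- sim[c("cohort", "panel", "unit_costs", "population")]
    truth <- sim$truth
  } else {
    tables <- read_tables(config$inputs)
    truth <- NULL
  }
  data <- analysis_table(tables$cohort, tables$panel)
  data <- apply_filters(data, config$filters)
  adjusters <- intersect(config$adjusters, names(data))
  boot_seed <- substream_seed(config$seed, "bootstrap")
  n_draws <- config$n_draws

  table2 <- list(); trends <- list(); projections <- list()
  fits_cost <- list()
  for (oc in names(outcome_columns())) {
    cols <- outcome_columns()[[oc]]
    for (measure in names(cols)) {
      spec <- model_spec(outcome = cols[[measure]], adjusters = adjusters)
      fit <- fit_quasipoisson(build_design(data, spec))
      std <- standardized_cis(fit, n_draws = n_draws,
                              seed = substream_seed(boot_seed, paste(oc, measure)))
      eff <- percent_differences(fit)
      tab <- merge(std, eff[, c("category", "percent_diff", "ci_low", "ci_high")],
                   by = "category", suffixes = c("", "_pct"))
      tab <- tab[match(intersect(fine_bmi_levels(), tab$category), tab$category), ]
      tab <- cbind(outcome = oc, measure = measure, tab)
      table2[[paste(oc, measure)]] <- tab
      tr <- trend_above_20(data, spec)
      trends[[paste(oc, measure)]] <- data.frame(
        outcome = oc, measure = measure, slope = tr$slope,
        pct_per_2kgm2 = tr$pct_per_2, ci_low = tr$ci[1], ci_high = tr$ci[2])
      if (measure == "cost") fits_cost[[oc]] <- fit
    }
  }
  table2 <- do.call(rbind, c(table2, make.row.names = FALSE))
  trends <- do.call(rbind, c(trends, make.row.names = FALSE))

  for (oc in c("consultations", "prescriptions")) {
    proj <- bootstrap_projection(fits_cost[[oc]], tables$population,
                                 n_draws = n_draws,
                                 seed = substream_seed(boot_seed, paste("proj", oc)))
    projections[[oc]] <- cbind(outcome = oc, proj)
  }
  table3 <- do.call(rbind, c(projections, make.row.names = FALSE))

  # therapeutic-use attribution (prescription cost models per use)
  use_fits <- lapply(stats::setNames(rx_use_levels(), rx_use_levels()),
                     function(use) {
    spec <- model_spec(outcome = paste0("rx_cost_", use), adjusters = adjusters)
    fit_quasipoisson(build_design(data, spec))
  })
  fig2 <- therapeutic_attribution(use_fits, tables$population)

  # diabetes mediation on consultation and prescription costs
  med <- list()
  for (oc in c("consultations", "prescriptions")) {
    cols <- outcome_columns()[[oc]]
    spec_adj <- model_spec(outcome = cols[["cost"]],
                           adjusters = c(adjusters, "diabetes_flag"))
    fit_adj <- fit_quasipoisson(build_design(data, spec_adj))
    base_proj <- project_costs(standardize_all(fits_cost[[oc]]), tables$population)
    adj_proj <- project_costs(standardize_all(fit_adj), tables$population)
    m <- mediation_proportion(base_proj, adj_proj, outcome = oc)
    med[[oc]] <- data.frame(outcome = oc, p_base = m$p_base, p_adj = m$p_adj,
                            explained = m$explained,
                            explained_absolute = m$explained_absolute)
  }
  mediation <- do.call(rbind, c(med, make.row.names = FALSE))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table2, file.path(out, "table2.csv"), row.names = FALSE)
  utils::write.csv(trends, file.path(out, "trends.csv"), row.names = FALSE)
  utils::write.csv(table3, file.path(out, "table3.csv"), row.names = FALSE)
  utils::write.csv(fig2, file.path(out, "fig2_attribution.csv"), row.names = FALSE)
  utils::write.csv(mediation, file.path(out, "mediation.csv"), row.names = FALSE)
  result_tables <- list(table2 = table2, trends = trends, table3 = table3,
                        fig2 = fig2, mediation = mediation)

  if (!is.null(truth)) {
    agg <- function(oc) table3$attributable_prop[table3$outcome == oc &
                                                   table3$category == ">=25"]
    tve <- data.frame(
      quantity = c("consult_cost_pct_per_2kgm2", "rx_cost_pct_per_2kgm2",
                   "consult_attributable_prop", "rx_attributable_prop"),
      truth = c(truth$pct_per_2kgm2[["consult"]], truth$pct_per_2kgm2[["rx"]],
                truth$attributable_proportion$consult_cost,
                truth$attributable_proportion$rx_cost),
      estimate = c(trends$pct_per_2kgm2[trends$outcome == "consultations" &
                                          trends$measure == "cost"],
                   trends$pct_per_2kgm2[trends$outcome == "prescriptions" &
                                          trends$measure == "cost"],
                   agg("consultations"), agg("prescriptions")),
      ci_low = c(trends$ci_low[trends$outcome == "consultations" &
                                 trends$measure == "cost"],
                 trends$ci_low[trends$outcome == "prescriptions" &
                                 trends$measure == "cost"],
                 table3$prop_ci_low[table3$outcome == "consultations" &
                                      table3$category == ">=25"],
                 table3$prop_ci_low[table3$outcome == "prescriptions" &
                                      table3$category == ">=25"]),
      ci_high = c(trends$ci_high[trends$outcome == "consultations" &
                                   trends$measure == "cost"],
                  trends$ci_high[trends$outcome == "prescriptions" &
                                   trends$measure == "cost"],
                  table3$prop_ci_high[table3$outcome == "consultations" &
                                        table3$category == ">=25"],
                  table3$prop_ci_high[table3$outcome == "prescriptions" &
                                        table3$category == ">=25"]))
    utils::write.csv(tve, file.path(out, "truth_vs_estimate.csv"),
                     row.names = FALSE)
    result_tables$truth_vs_estimate <- tve
  }

  manifest <- list(package = "bmicost",
                   version = as.character(utils::packageVersion("bmicost")),
                   seed = config$seed, n_draws = n_draws,
                   mode = if (is.null(truth)) "inputs" else "simulate")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(structure(out, tables = result_tables))
}
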