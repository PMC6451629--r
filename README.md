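# bmicost

An R package for quantifying how body mass index (BMI) relates to the use
and costs of primary care — consultations, prescription medications, and
diagnostic tests — in cohorts of older women followed through linked
primary-care records, and for projecting the costs attributable to excess
weight to a national population. It is aimed at health economists and
epidemiologists who need the full published-style pipeline (per-band
effect tables, trends, population projections, mediation decomposition)
as tested, reusable code rather than a one-off script.

## What it computes

The core model is a quasi-likelihood GLM with log link and Poisson-like
variance, for counts and for costs alike:

    log mu_it = b0 + sum_k b_k 1[BMI_i in band k] + g' z_it,
    Var(y_it) = phi * mu_it,

fitted on person-year panels with Pearson-estimated overdispersion `phi`
and cluster-robust (person-level) sandwich variance with a `G/(G-1)`
small-sample factor. On top of the fit:

* **Floated percentage differences** per BMI band: quasi-variances `v_k`
  (including the reference band) minimising the log-scale pairwise error
  `sum_{i<j} (log(v_i + v_j) - log Var(l_i - l_j))^2`, giving
  group-specific 99% CIs so that any two bands can be compared.
* **Trends per 2 kg/m² above 20 kg/m²**: `100 * (exp(2b) - 1)` with
  conventional cluster-robust CIs.
* **Standardized annual rates and costs** by g-computation over the
  fitted person-years (BMI band set counterfactually, follow-up fraction
  set to 1), with 99% parametric-bootstrap percentile intervals from
  multivariate-normal parameter draws.
* **Population projection**: per-person standardized costs combined over
  a population BMI-distribution table (default: 6.63 million women aged
  55–79 in five coarse bands), reporting total costs `T_k = N_k c_k`,
  excess-weight-attributable costs `A_k = N_k (c_k - c_ref)` relative to
  the weighted 20–24.9 reference, attributable proportions, and a
  therapeutic-use breakdown of attributable prescription costs.
* **Diabetes mediation** by the adjusted-model difference: the relative
  reduction in the attributable proportion when diabetes status is added
  as a covariate.
* **A synthetic cohort generator** with known ground truth (calibrated
  BMI mixture, negative-binomial counts with person frailty, exact
  count-times-unit-cost bookkeeping, BMI-dependent diabetes onset), so
  every stage above is testable end to end.

## Worked example

```r
library(bmicost)

cfg  <- simulation_config(n_women = 2000, years = 4, seed = 7)
sim  <- simulate_study(cfg)
data <- analysis_table(sim$cohort, sim$panel)

spec <- model_spec("rx_cost", adjusters = c("age_band", "deprivation_third",
                                            "smoking", "year_index",
                                            "fraction_observed"))
fit  <- fit_quasipoisson(build_design(data, spec))

percent_differences(fit)[, c("category", "percent_diff", "ci_low", "ci_high")]
#>      category percent_diff ci_low ci_high
#> 1 18.5 to <20        -7.51 -13.76  -0.811
#> 2 20 to <22.5         0.00  -4.25   4.440
#> 3 22.5 to <25        13.74   9.11  18.567
#> 4 25 to <27.5        25.83  21.06  30.789
#> 5 27.5 to <30        44.29  37.92  50.969
#> 6   30 to <35        71.96  62.28  82.214
#> 7   35 to <40       132.69 110.31 157.448
#> 8        >=40       326.34 242.14 431.261

trend_above_20(data, spec)$pct_per_2
#> [1] 12.32805

proj <- bootstrap_projection(fit, sim$population, n_draws = 500, seed = 1)
proj[proj$category == ">=25", c("attributable_m", "total_cost_m", "attributable_pct")]
#>   attributable_m total_cost_m attributable_pct
#> 6       562.4537     1590.362               35
```

Reading this: annual prescription costs rise steeply across BMI bands
relative to the 20 to <22.5 reference (floated 99% CIs, so the reference
row has its own interval); the per-2 kg/m² trend above 20 kg/m² is
+12.3% in this small simulated cohort (the configured direct effect is
+9.9%, and the default generator routes an additional component through
BMI-dependent diabetes); and projected to the population table, about
£562M of £1,590M in annual prescription costs among women with BMI ≥ 25
— 35% — is attributable to excess weight.

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow (simulate, fit, per-band effects, projection,
mediation), writing their tables under `results/`.

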