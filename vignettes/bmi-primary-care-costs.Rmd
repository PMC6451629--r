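---
title: "Modelling BMI and primary-care use and costs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling BMI and primary-care use and costs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmicost)
```

## The problem

Excess body weight is associated with more primary-care consultations,
more prescription items, and higher costs. Quantifying that association in
a cohort of older women requires a chain of methods: overdispersed count
and cost regression on person-year panels, variance estimation that
respects repeated observation of the same woman, confidence intervals that
allow any two BMI bands to be compared (not just each band against the
reference), standardization of per-band estimates to a common covariate
distribution, projection of per-person costs to a national population, and
a decomposition of the excess costs by diabetes status. `bmicost`
implements that chain end to end, together with a synthetic cohort
generator with known ground truth so that every stage is testable without
access to restricted patient records.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers, and all computation lives in
the package functions they call.

## The regression model

For person $i$ in financial year $t$, let $y_{it}$ be a count (or a cost
in GBP) accrued over the observed fraction $f_{it} \in (0, 1]$ of the
year. The model is a quasi-likelihood generalised linear model with log
link and variance proportional to the mean,

$$\log \mu_{it} = \beta_0 + \sum_k \beta_k \, [x_i \in \text{band}_k]
  + \gamma' z_{it}, \qquad \operatorname{Var}(y_{it}) = \phi \, \mu_{it},$$

where the exposure is either the eight-band BMI categorisation (reference
20 to <22.5 kg/m²) or BMI entered linearly on the subset with BMI > 20,
and $z_{it}$ collects the adjusters: age band, region, deprivation third,
education, smoking, alcohol, parity, age at first birth, financial year,
and the follow-up fraction $f_{it}$. Fitting is by iteratively reweighted
least squares (relative deviance change below $10^{-8}$, at most 100
iterations, the standard Poisson starting values $\mu^{(0)} = y + 0.1$);
the same score equations are valid for non-integer costs, so a single
family serves both counts and costs. The dispersion $\phi$ is estimated
from the Pearson statistic, $\hat\phi = X^2 / (n - p)$, which remains
well defined for continuous responses (a deviance-based estimator would
not be). On the cost scale $\hat\phi$ absorbs the currency unit, so
values in the tens are expected and are not a warning sign.

Three deliberate modelling choices:

* **Costs are modelled directly on the currency scale** with the same
  variance-proportional-to-mean family as counts; no two-part or gamma
  model. Where unit costs are constant within a service category, a cost
  is a fixed multiple of a count and the quasi-Poisson score equations are
  exactly scale-equivariant, which the tests exploit.
* **The follow-up fraction enters as a linear covariate, not an offset.**
  Predictions are standardized at $f = 1$, which defines "annual"
  estimates. The generator, by contrast, scales the mean multiplicatively
  by $f$; this mismatch is deliberate, so that the tests can verify that
  standardization at $f = 1$ annualises correctly even under mild model
  misspecification.
* **`missing` is an ordinary covariate level.** Missing covariate values
  are assigned to their own category, which is never the reference.

## Cluster-robust variance

Outcomes for the same woman are correlated across years, so all inference
uses the sandwich estimator with person-level clusters:

$$\hat V = \frac{G}{G-1} \, B^{-1} \Big( \sum_g s_g s_g' \Big) B^{-1},
  \qquad B = X'WX, \quad s_g = \sum_{i \in g} x_i (y_i - \hat\mu_i),$$

with $G$ the number of women. No dispersion factor appears in the meat
(the scores carry it implicitly), and the only small-sample correction is
the $G/(G-1)$ factor, the simplest widely used choice; results are
therefore exactly reproducible from the formula. The test suite verifies
the implementation against a two-cluster hand computation, against
`sandwich::vcovCL`, and — in simulation with person frailty — that the
cluster-robust 99% intervals for the BMI trend achieve near-nominal
coverage while model-based intervals would not.

## Floated (quasi-variance) confidence intervals

Reporting one effect per BMI band against a fixed reference makes
non-reference comparisons awkward: the covariance with the reference is
buried in the contrast variances. Floated CIs assign each band $k$ —
including the reference — a quasi-variance $v_k$ such that
$\operatorname{Var}(\hat\lambda_i - \hat\lambda_j) \approx v_i + v_j$ for
every pair. The package minimises the standard scale-free objective

$$\sum_{i<j} \big( \log(v_i + v_j) - \log \widehat{\operatorname{Var}}
  (\hat\lambda_i - \hat\lambda_j) \big)^2$$

by BFGS on $\log v$ with analytic gradients and a deterministic
multi-start (a linear least-squares solution of $v_i + v_j = D_{ij}$, the
shared-reference decomposition, and a flat start), because the log
parameterisation has a vanishing gradient at $v \to 0$ and a single start
can stall there. Squared error of *log* variances (not raw variances) is
used because it is scale-free and standard in the quasi-variance
literature. When the contrast covariance has the exact shared-reference
structure $\operatorname{Var}(\hat\lambda_j) = v_0 + v_j$,
$\operatorname{Cov}(\hat\lambda_i, \hat\lambda_j) = v_0$, the solution is
recovered exactly; the achieved maximum relative error of the pairwise
approximation is attached to every result as a diagnostic. All 99%
intervals use the normal quantile $z = 2.5758$; no $t$ correction is
applied because cluster counts in intended use are in the thousands.
Trend CIs are conventional cluster-robust intervals; only per-band effects
are floated.

## Standardization and projection

Standardized annual estimates use g-computation over the fitted
person-years: every person-year keeps its covariates, the BMI band is set
to $k$ and the follow-up fraction to 1, and
$c_k = \tfrac1n \sum \exp(x'\hat\beta)$. The standardization population is
person-years, not persons, matching the analysis unit. Uncertainty comes
from parameter simulation: $\beta^* \sim N(\hat\beta, \hat V_{cluster})$,
$c_k$ recomputed per draw, 99% interval from the 0.5 and 99.5 percentiles
(10,000 draws by default; the acceptance script uses 500). A covariance
with small negative eigenvalues (numerical noise) is repaired by flooring
them at zero; a genuinely indefinite matrix is an error.

Projection combines fine-band standardized costs $c_k$ into the five
coarse bands with configurable fine weights, multiplies by the population
counts $N_k$ (6.63 million women in the default fixture: 2.83, 2.28,
1.06, 0.30, 0.16 million), and reports totals $T_k = N_k c_k$,
attributable costs $A_k = N_k (c_k - c_{ref})$ and proportions
$P_k = A_k / T_k$, plus the $\geq 25$ aggregate. The reference cost is the
weighted average of the 20 to <22.5 and 22.5 to <25 bands, using the <25
band's weights restricted and renormalised to those two bands. Fine
weights default to equal shares within each coarse band: the survey
weights behind any particular published projection are an input, never
hard-coded, and this approximation affects only fixture calibration, not
algorithmic correctness. Population counts are treated as fixed in the
bootstrap — the intervals reflect model-parameter uncertainty only.
Negative attributable costs are retained, not truncated. Reported
percentages round half away from zero; full precision is kept internally.

## Diabetes mediation

The mediation analysis is the simple adjusted-difference heuristic, and
only that: the attributable proportion $P$ from the primary model is
compared with $P_{adj}$ from the same model plus the diabetes flag, and
the proportion explained is $E = (P - P_{adj}) / P$ on the $\geq 25$
aggregate. Because it is ambiguous whether such a decomposition should be
read on proportions or on absolute attributable costs, both are reported,
clearly labelled, with the proportion-based figure as the primary one.
The diabetes flag turns on in the year evidence first appears and stays
on. No causal-mediation estimands (natural direct/indirect effects) are
attempted.

## The synthetic-data generator

The generator emulates the structure of the intended data, with every
parameter recorded in a ground-truth record:

* **BMI** is drawn from a two-component normal mixture truncated at 18.5
  kg/m² (weight 0.637 on $N(24.59, 3.95^2)$, rest $N(23.52, 9.55^2)$),
  calibrated once so the five coarse-band shares are 47 / 36 / 11.8 /
  3.4 / 1.8 percent — the profile of older English women. A single
  narrow-tailed component cannot produce both the 47% below 25 and a
  realistic $\geq 40$ band, hence the broad second component.
* **The BMI-rate relationship is piecewise log-linear: flat below 20
  kg/m², linear above.** Placing the knee at 20 makes the linear-above-20
  trend model correctly specified, so parameter-recovery tests check
  genuine nominal coverage rather than a built-in attenuation. The cost is
  that the 18.5 to <20 band sits at the flat reference level rather than
  slightly above it; the optional `underweight_rx_excess` parameter
  (default 0) recreates elevated underweight prescription costs when
  wanted. Default slopes imply cost trends of +5.2% (consultations) and
  +9.9% (prescriptions) per 2 kg/m², with no test-cost trend.
* **Counts are negative-binomial** with variance $\phi\mu$ ($\phi = 1.5$
  by default), multiplied by a log-normal person frailty
  (`frailty_sd = 0.25`) that creates the within-person correlation the
  sandwich variance must absorb. The frailty magnitude is a free choice —
  nothing in the emulated setting pins down the within-person correlation
  — and is therefore reported in `truth.json` and never asserted against
  external values.
* **Covariates** are drawn independently of BMI with fixed category
  probabilities; default log effects are centred so each covariate's
  population-mean multiplier is 1, keeping `baseline_rate` interpretable
  as the marginal mean annual count in the reference band (7.0
  consultations, 27.0 items, 8.0 tests). Missing values are injected at
  rate 0.02 per covariate and contribute a zero log effect.
* **Diabetes** onset follows an annual logistic hazard
  $\operatorname{logit}^{-1}(-7.3 + 0.13 \cdot \text{BMI})$, giving about
  12% of women some evidence of diabetes over six years; the flag is
  carried forward and multiplies outcome means (by default concentrated
  on the drugs-in-diabetes therapeutic category).
* **Follow-up** ends mid-year with annual probability 0.05; the final
  partial year has a uniform fraction on $[1/12, 1]$. Costs equal counts
  times unit costs exactly, by construction.

The ground-truth record computes, by quadrature over the mixture density,
the true standardized annual mean per band (including the expected
flagged-year fraction for the diabetes factor and the closed-form frailty
and covariate-mix constants) and the implied true attributable
proportions under a given population table.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: confounding structure (covariates are
independent of BMI unless a test induces dependence deliberately),
measurement error in self-reported BMI, non-random dropout, secular
trends in prescribing, heavy-tailed cost distributions beyond what
negative-binomial counts times fixed unit costs produce, and real
survey-based fine weights within coarse BMI bands.

## Calibration notes and problem sizes

Two published-scale calibrations cannot hold simultaneously under equal
fine weights: with the prescription trend set to +9.9% per 2 kg/m², the
implied true attributable prescription proportion is 0.3015 rather than
0.31. The recovery tests therefore assert coverage of the configured
truth computed from the ground-truth record, not of a transcribed number.

Simulation-based checks use sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping the default suite quick: 100
replicates of 5,000 women x 6 years for trend recovery and for bootstrap
coverage of the attributable proportion (500 parameter draws per
replicate), roughly 50,000 person-years for the dispersion-recovery and
mediation-limit checks, and 1,000 replicates for the heterogeneity-test
type-I error. The mediation-limit and recovery scenarios switch the
diabetes cost effect off so the closed-form truths are exact; the
mediation workflow scenario instead routes part of the BMI effect through
diabetes, with the direct slope reduced so total trends keep their usual
magnitude.

## Known limitations

* The quasi-Poisson cost model assumes variance proportional to the mean
  on the currency scale; real cost data are often heavier-tailed, and the
  package deliberately offers no two-part or gamma alternative.
* Subgroup heterogeneity assumes independent subgroups (they partition
  persons) and large-sample normality of the slope estimates.
* The projection assumes the standardized per-person costs transport to
  the external population conditional on BMI band — there is no
  reweighting for covariate differences between cohort and population.
* The adjusted-difference mediation figure is a descriptive
  decomposition, not a causal mediation effect.
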