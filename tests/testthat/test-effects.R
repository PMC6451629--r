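# Category effect measures: quasi-variances, floated CIs, the per-2 kg/m2
# trend, measured-BMI remapping, subgroup heterogeneity.

test_that("quasi-variances recover the shared-reference structure exactly", {
  v0 <- 0.013
  vj <- c(a = 0.041, b = 0.096, c = 0.022, d = 0.067)
  V <- matrix(v0, 4, 4) + diag(vj)
  dimnames(V) <- list(names(vj), names(vj))
  fe <- floated_variances(V)
  expect_equal(fe$floated_var, unname(c(v0, vj)), tolerance = 1e-6)
  expect_lt(attr(fe, "max_relative_error"), 1e-6)
})

test_that("quasi-variance solution matches an independent minimizer", {
  set.seed(31)
  for (rep in 1:3) {
    A <- matrix(rnorm(9, sd = 0.2), 3, 3)
    V <- crossprod(A) + diag(0.05, 3)
    colnames(V) <- rownames(V) <- paste0("g", 1:3)
    fe <- floated_variances(V)
    oracle <- qvar_oracle(V)
    obj <- qvar_objective(V)
    # the package optimum is at least as good as the oracle's
    expect_lte(obj(fe$floated_var), obj(oracle$v) * (1 + 1e-4) + 1e-10)
    # and the achieved pairwise approximation errors agree
    pair_err_oracle <- max(abs(outer(oracle$v, oracle$v, "+")[
      upper.tri(diag(4))] / qvar_pairwise(V) - 1))
    expect_lt(abs(attr(fe, "max_relative_error") - pair_err_oracle), 1e-2)
  }
  expect_error(floated_variances(matrix(0.1, 1, 1)), "3 categories")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(floated_variances(bad), "positive semi-definite")
})

test_that("reference floated interval reproduces the +/-2% fixture", {
  # shared-reference covariance whose reference quasi-variance is 0.000061
  v0 <- 0.000061
  vj <- c(0.0003, 0.0005, 0.0002, 0.0004, 0.0009, 0.0015, 0.0030)
  V <- matrix(v0, 7, 7) + diag(vj)
  colnames(V) <- rownames(V) <- paste0("band", 1:7)
  fe <- floated_variances(V)
  ref <- fe[fe$category == "reference", ]
  expect_equal(ref$percent_diff, 0)
  expect_equal(ref$ci_low, -2.0, tolerance = 0.05)
  expect_equal(ref$ci_high, 2.0, tolerance = 0.05)
})

test_that("percent differences are 100*(RR-1) with floated bands in order", {
  d <- small_analysis_table(500, 3, seed = 32)
  fit <- fit_quasipoisson(build_design(d, model_spec("consult_cost",
                                                     adjusters = short_adjusters())))
  eff <- percent_differences(fit)
  expect_identical(eff$category, fine_bmi_levels())
  expect_equal(eff$percent_diff, 100 * (exp(eff$lambda) - 1))
  expect_equal(eff$lambda[eff$category == reference_fine_level()], 0)
  expect_true(all(eff$floated_var > 0))
  expect_true(all(eff$ci_low < eff$percent_diff & eff$percent_diff < eff$ci_high))
  # a top-band log effect of log(1.645) is +64.5%
  fe <- floated_variances(diag(0.01, 3), lambda = c(a = 0, b = 0.1, c = log(1.645)))
  expect_equal(fe$percent_diff[fe$category == "c"], 64.5, tolerance = 1e-10)
})

test_that("floated CI half-widths are near conventional contrast half-widths", {
  d <- small_analysis_table(800, 3, seed = 33)
  fit <- fit_quasipoisson(build_design(d, model_spec("consult_count",
                                                     adjusters = short_adjusters())))
  eff <- percent_differences(fit)
  idx <- grep("^bmi_category_fine", names(fit$beta))
  conv_se <- sqrt(diag(fit$cov_cluster)[idx])
  names(conv_se) <- sub("^bmi_category_fine", "", names(conv_se))
  non_ref <- eff[eff$category != reference_fine_level(), ]
  ratio <- sqrt(non_ref$floated_var + eff$floated_var[eff$category == reference_fine_level()]) /
    conv_se[non_ref$category]
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("trend per 2 kg/m2: formula, restriction, and the 9.9% fixture", {
  expect_equal(100 * (exp(2 * 0.047203) - 1), 9.9, tolerance = 0.01)
  d <- small_analysis_table(800, 3, seed = 34,
                            slope_per_unit_bmi = c(consult = 0, rx = 0, test = 0))
  tr <- trend_above_20(d, model_spec("consult_count", adjusters = short_adjusters()))
  expect_true(all(tr$fit$design$data$bmi > 20))
  expect_lt(tr$ci[1], 0)
  expect_gt(tr$ci[2], 0)
  expect_equal(tr$pct_per_2, 100 * (exp(2 * tr$slope) - 1))
})

test_that("measured-BMI remapping: identity and affine reparameterization", {
  d <- small_analysis_table(500, 2, seed = 35)
  mids <- c("18.5 to <20" = 19.25, "20 to <22.5" = 21.25, "22.5 to <25" = 23.75,
            "25 to <27.5" = 26.25, "27.5 to <30" = 28.75, "30 to <35" = 32.5,
            "35 to <40" = 37.5, ">=40" = 42)
  d_mid <- remap_measured_bmi(d, mids)
  spec <- model_spec("consult_count", adjusters = c("age_band", "fraction_observed"))
  tr1 <- trend_above_20(d_mid, spec)
  # identity: remapping to the same values changes nothing
  tr_same <- trend_above_20(remap_measured_bmi(d_mid, mids), spec)
  expect_equal(tr_same$slope, tr1$slope)
  # affine compression of the mapped values inflates the slope by 1/0.8
  mids2 <- 21.25 + 0.8 * (mids - 21.25)
  names(mids2) <- names(mids)
  tr2 <- trend_above_20(remap_measured_bmi(d, mids2), spec)
  expect_equal(tr2$slope, tr1$slope / 0.8, tolerance = 1e-6)
  expect_error(remap_measured_bmi(d, mids[-1]), "18.5 to <20")
})

test_that("heterogeneity Q: null, hand arithmetic, shift invariance", {
  same <- subgroup_heterogeneity(rep(0.04, 4), rep(0.002, 4))
  expect_equal(same$Q, 0)
  expect_equal(same$p_value, 1)
  two <- subgroup_heterogeneity(c(0, 0.1), c(0.001, 0.001))
  expect_equal(two$Q, 5, tolerance = 1e-12)
  expect_equal(two$df, 1)
  shifted <- subgroup_heterogeneity(c(0, 0.1) + 7, c(0.001, 0.001))
  expect_equal(shifted$Q, two$Q)
  expect_error(subgroup_heterogeneity(c(0, 0.1), c(0.001, 0)), "positive")
})
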