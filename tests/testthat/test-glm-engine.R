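# Quasi-Poisson engine: design coding, closed-form and oracle checks of
# the fit, Pearson dispersion, and the cluster-robust sandwich.

test_that("design coding: reference levels, missing level, subset filter", {
  d <- small_analysis_table(400, 2, seed = 21, missing_covariate_prob = 0.04)
  spec <- model_spec("consult_count", exposure = "none",
                     adjusters = "deprivation_third")
  des <- build_design(d, spec)
  expect_equal(ncol(des$X), 1 + (nlevels(des$data$deprivation_third) - 1))
  # "missing" is a level but never the reference
  expect_true("missing" %in% levels(des$data$deprivation_third))
  expect_false(levels(des$data$deprivation_third)[1] == "missing")
  miss_col <- grep("missing", colnames(des$X), value = TRUE)
  expect_length(miss_col, 1)
  expect_lt(abs(mean(des$X[, miss_col]) - 0.04), 3 * sqrt(0.04 * 0.96 / nrow(d)))

  spec_sub <- model_spec("consult_count", exposure = "none",
                         adjusters = "smoking", subset = "bmi > 20")
  des_sub <- build_design(d, spec_sub)
  expect_true(all(des_sub$data$bmi > 20))
  expect_equal(nrow(des_sub$X), sum(d$bmi > 20))
  expect_error(build_design(d, model_spec("consult_count", exposure = "none",
                                          subset = "bmi > 99")),
               "no rows")
})

test_that("rank deficiency is reported with the collinear column", {
  d <- small_analysis_table(200, 2, seed = 22)
  d$copy_of_bmi <- d$bmi
  spec <- model_spec("consult_count", exposure = "bmi_linear_above20",
                     adjusters = "copy_of_bmi")
  expect_error(build_design(d, spec), "copy_of_bmi")
})

test_that("closed forms: intercept-only mean matching and saturated ratios", {
  d0 <- data.frame(person_id = c(1, 2), year_index = 1,
                   fraction_observed = 1, y = c(2, 4))
  spec <- model_spec("y", exposure = "none")
  fit <- fit_quasipoisson(build_design(d0, spec))
  expect_equal(unname(fit$beta[1]), log(3), tolerance = 1e-8)

  d1 <- data.frame(person_id = 1:40, year_index = 1, fraction_observed = 1,
                   grp = rep(c("a", "b"), each = 20),
                   y = c(rpois(20, 4) + 1, rpois(20, 9) + 1))
  fit1 <- fit_quasipoisson(build_design(d1, model_spec("y", exposure = "none",
                                                       adjusters = "grp")))
  mean_a <- mean(d1$y[d1$grp == "a"]); mean_b <- mean(d1$y[d1$grp == "b"])
  expect_equal(unname(fit1$beta[["grpb"]]), log(mean_b / mean_a),
               tolerance = 1e-8)
})

test_that("coefficients match an independent Newton-Raphson oracle to 1e-6", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 200
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("i", "a", "b", "c")
    y <- rpois(n, exp(0.8 + 0.3 * X[, 2] - 0.2 * X[, 3]))
    d <- data.frame(person_id = rep(1:50, each = 4), year_index = 1,
                    fraction_observed = 1, y = y,
                    a = X[, 2], b = X[, 3], cc = X[, 4])
    des <- build_design(d, model_spec("y", exposure = "none",
                                      adjusters = c("a", "b", "cc")))
    fit <- fit_quasipoisson(des)
    oracle <- nr_poisson(des$X, des$y)
    expect_lt(max(abs(unname(fit$beta) - oracle)), 1e-6)
  }
})

test_that("mean preservation and degenerate responses", {
  d <- small_analysis_table(300, 2, seed = 24)
  fit <- fit_quasipoisson(build_design(d, model_spec("rx_cost",
                                                     adjusters = short_adjusters())))
  expect_lt(abs(sum(fit$fitted) - sum(d$rx_cost)) / sum(d$rx_cost), 1e-6)
  d$zero <- 0
  expect_error(fit_quasipoisson(build_design(d, model_spec("zero", exposure = "none"))),
               "all-zero")
})

test_that("cluster sandwich matches a hand computation on a 2-cluster toy", {
  d <- data.frame(person_id = c(1, 1, 2, 2), year_index = c(1, 2, 1, 2),
                  fraction_observed = 1,
                  x = c(0, 1, 0, 1), y = c(3, 5, 2, 7))
  des <- build_design(d, model_spec("y", exposure = "none", adjusters = "x"))
  fit <- fit_quasipoisson(des)
  mu <- fit$fitted
  X <- des$X
  B <- matrix(0, 2, 2)
  for (i in 1:4) B <- B + mu[i] * X[i, ] %*% t(X[i, ])
  s1 <- (d$y[1] - mu[1]) * X[1, ] + (d$y[2] - mu[2]) * X[2, ]
  s2 <- (d$y[3] - mu[3]) * X[3, ] + (d$y[4] - mu[4]) * X[4, ]
  meat <- s1 %*% t(s1) + s2 %*% t(s2)
  V_hand <- solve(B) %*% meat %*% solve(B) * 2 / (2 - 1)
  expect_equal(unname(fit$cov_cluster), unname(V_hand), tolerance = 1e-6)
  des1 <- des
  des1$cluster <- rep(1, 4)
  expect_error(cluster_robust_cov(fit, des1), "2 clusters")
})

test_that("duplicating rows within clusters leaves sandwich SEs unchanged", {
  d <- small_analysis_table(150, 2, seed = 25)
  spec <- model_spec("consult_count", adjusters = "fraction_observed")
  fit1 <- fit_quasipoisson(build_design(d, spec))
  k <- 3
  dd <- d[rep(seq_len(nrow(d)), each = k), ]
  fitk <- fit_quasipoisson(build_design(dd, spec))
  expect_equal(fitk$beta, fit1$beta, tolerance = 1e-6)
  expect_equal(sqrt(diag(fitk$cov_cluster)), sqrt(diag(fit1$cov_cluster)),
               tolerance = 1e-6)
  # model-based SEs shrink by sqrt(k) (dispersion is slightly deflated by
  # the larger n - p denominator; compare via the bread alone)
  expect_equal(sqrt(diag(fitk$cov_model / fitk$dispersion)),
               sqrt(diag(fit1$cov_model / fit1$dispersion)) / sqrt(k),
               tolerance = 1e-6)
})

test_that("sandwich agrees with sandwich::vcovCL on a Poisson fit", {
  skip_if_not_installed("sandwich")
  d <- small_analysis_table(300, 3, seed = 26)
  spec <- model_spec("consult_count", adjusters = c("age_band", "fraction_observed"))
  des <- build_design(d, spec)
  fit <- fit_quasipoisson(des)
  g <- stats::glm(consult_count ~ bmi_category_fine + age_band + fraction_observed,
                  data = des$data, family = poisson(),
                  control = list(epsilon = 1e-14, maxit = 200))
  Vs <- sandwich::vcovCL(g, cluster = des$cluster, type = "HC0", cadjust = TRUE)
  scale <- max(abs(Vs))
  expect_lt(max(abs(fit$cov_cluster[colnames(Vs), colnames(Vs)] - Vs)) / scale,
            1e-5)
})

test_that("single-row clusters with Poisson data: sandwich near model-based SEs", {
  set.seed(27)
  n <- 8000
  d <- data.frame(person_id = seq_len(n), year_index = 1, fraction_observed = 1,
                  x = rnorm(n))
  d$y <- rpois(n, exp(1 + 0.2 * d$x))
  fit <- fit_quasipoisson(build_design(d, model_spec("y", exposure = "none",
                                                     adjusters = "x")))
  expect_lt(max(abs(sqrt(diag(fit$cov_cluster)) / sqrt(diag(fit$cov_model)) - 1)),
            0.1)
})

test_that("predictions: reference profile, training consistency, link identity", {
  d <- small_analysis_table(400, 2, seed = 28)
  spec <- model_spec("consult_count", adjusters = short_adjusters())
  fit <- fit_quasipoisson(build_design(d, spec))
  # training rows at their observed fractions reproduce fitted means
  pred <- predict_mean(fit, fit$design$data, fraction_observed = NULL)
  expect_equal(pred, unname(fit$fitted), tolerance = 1e-10)
  # ratio between a band profile and the reference equals exp(beta_k)
  row <- fit$design$data[1, ]
  row_ref <- row; row_ref$bmi_category_fine <- reference_fine_level()
  row_k <- row; row_k$bmi_category_fine <- ">=40"
  ratio <- predict_mean(fit, row_k) / predict_mean(fit, row_ref)
  expect_equal(unname(ratio), unname(exp(fit$beta[["bmi_category_fine>=40"]])),
               tolerance = 1e-10)
  bad <- row; bad$smoking <- "vaper"
  expect_error(predict_mean(fit, bad), "vaper")
})
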