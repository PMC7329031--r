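test_that("per-capita growth rates are log first differences", {
  expect_equal(per_capita_growth(c(5, 5, 5)), c(0, 0))
  expect_equal(per_capita_growth(c(100, 200, 400)), rep(log(2), 2))
  expect_equal(per_capita_growth(c(100, 50)), -log(2))
  expect_error(per_capita_growth(c(1, 0, 2)), "n > 0")
})

test_that("carrying capacity is linear in the covariates with a positivity guard", {
  expect_equal(carrying_capacity(c(k0 = 500), palm = 13, soi = -2), 500)
  expect_equal(carrying_capacity(c(k0 = 0, k_f = 10), palm = 40), 400)
  expect_error(carrying_capacity(c(k0 = 100, k_c = -200), soi = 0.6),
               "invalid parameter region")
})

test_that("the Ricker step matches its closed form", {
  expect_equal(ricker_step(0.7, 1000, 1000), 1000)   # equilibrium
  expect_equal(ricker_step(0, 123, 500), 123)        # zero growth
  expect_equal(ricker_step(0.5, 500, 1000), 500 * exp(0.25))
  expect_error(ricker_step(0.5, -1, 100), "n_prev")
})

test_that("AICc matches the hand-evaluated small-sample formula", {
  # n = 22, k = 2, rss = 0.22: 22 ln(0.01) + 4 + 12/19
  expect_equal(aicc(22, 2, 0.22), -96.6821651443696, tolerance = 1e-12)
  # halving rss strictly improves; extra parameters strictly penalize
  expect_lt(aicc(22, 2, 0.11), aicc(22, 2, 0.22))
  expect_gt(aicc(22, 3, 0.22), aicc(22, 2, 0.22))
  expect_error(aicc(4, 3, 1), "n_obs")
})

test_that("Akaike weights renormalize evidence", {
  expect_equal(akaike_weights(c(-10, -10, -10)), rep(1 / 3, 3))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(akaike_weights(c(0, Inf)), c(1, 0))
  expect_error(akaike_weights(3), "two models")
})

test_that("prediction R2 matches hand arithmetic and is scale invariant", {
  x <- c(1, 2, 3)
  expect_equal(prediction_r2(x, x), 1)
  expect_equal(prediction_r2(x, rep(mean(x), 3)), 0)
  expect_equal(prediction_r2(x, c(3, 2, 1)), -3)
  set.seed(5)
  obs <- runif(15, 1, 3); pred <- obs + rnorm(15, 0, 0.3)
  expect_equal(prediction_r2(obs, pred), prediction_r2(7.3 * obs, 7.3 * pred))
  expect_error(prediction_r2(c(1, 1), c(1, 2)), "constant")
})

test_that("noise-free model output is refit to machine-level parameter recovery", {
  cov <- model_grid_covariates()
  truths <- list(
    constant = c(r_max = 0.4, k0 = 0.8),
    palm     = c(r_max = 0.4, k0 = 0.12, k_f = 0.015),
    soi      = c(r_max = 0.35, k0 = 0.5, k_c = -0.3),
    palm_soi = c(r_max = 0.4, k0 = 0.1, k_f = 0.012, k_c = -0.15)
  )
  for (form in names(truths)) {
    th <- truths[[form]]
    ser <- sim_ricker_series(th, form, cov, n0 = 0.05)
    fit <- fit_growth_model(ser, cov, k_form = form)
    expect_lt(max(abs(fit$coefficients[names(th)] - th) / abs(th)), 1e-6,
              label = paste("relative error for", form))
    expect_equal(fit$n_obs, 22L)
  }
})

test_that("degrees-of-freedom and covariate guards fail fast", {
  cov <- model_grid_covariates()[1:3, ]
  ser <- demographic_series(cov$time_ce, c(1, 2, 3))
  expect_error(fit_growth_model(ser, cov, k_form = "palm_soi"), "too few")
  ser2 <- demographic_series(model_grid_covariates()$time_ce,
                             seq(1, 2, length.out = 23))
  expect_error(fit_growth_model(ser2, k_form = "palm"), "covariates required")
})

test_that("the simulator closes the model equations exactly", {
  cov <- model_grid_covariates()
  th <- c(r_max = 0.4, k0 = 0.12, k_f = 0.015)
  tr <- simulate_trajectory(th, n0 = 0.05, covariates = cov, k_form = "palm")
  # generator/simulator equivalence
  ser <- sim_ricker_series(th, "palm", cov, n0 = 0.05)
  expect_equal(tr$n, ser$n, tolerance = 1e-14)
  # R_t from the simulated path equals the model right-hand side exactly
  R <- per_capita_growth(tr$n)
  K <- th[["k0"]] + th[["k_f"]] * cov$palm[-nrow(cov)]
  expect_equal(R, th[["r_max"]] * (1 - tr$n[-nrow(tr)] / K), tolerance = 1e-12)
  # fixed point and zero-growth degeneracies
  flat <- simulate_trajectory(c(r_max = 0.5, k0 = 700), n0 = 700,
                              times = cov$time_ce, k_form = "constant")
  expect_true(all(flat$n == 700))
  still <- simulate_trajectory(c(r_max = 0, k0 = 700), n0 = 123,
                               times = cov$time_ce, k_form = "constant")
  expect_true(all(still$n == 123))
})

test_that("trajectory bands degenerate and nest correctly", {
  cov <- model_grid_covariates()
  set.seed(31)
  ser <- sim_ricker_series(c(r_max = 0.4, k0 = 0.12, k_f = 0.015), "palm",
                           cov, n0 = 0.05, noise_sd = 0.02)
  fit <- fit_growth_model(ser, cov, k_form = "palm")
  # zero covariance collapses the band onto the point trajectory
  fit0 <- fit
  fit0$vcov[] <- 0
  b0 <- trajectory_ci(fit0, n0 = ser$n[1], covariates = cov, n_iter = 200,
                      seed = 1)
  expect_equal(b0$lo, b0$point, tolerance = 1e-12)
  expect_equal(b0$hi, b0$point, tolerance = 1e-12)
  # the 95% band encloses the 50% band at every time point
  b95 <- trajectory_ci(fit, n0 = ser$n[1], covariates = cov, n_iter = 2000,
                       level = 0.95, seed = 2)
  b50 <- trajectory_ci(fit, n0 = ser$n[1], covariates = cov, n_iter = 2000,
                       level = 0.50, seed = 2)
  expect_true(all(b95$lo <= b50$lo + 1e-12))
  expect_true(all(b95$hi >= b50$hi - 1e-12))
  expect_true(all(b95$lo <= b95$hi))
})

test_that("ratio regressions report the OLS line, F statistic and r2", {
  ratio <- seq(0.001, 0.2, length.out = 22)
  exact <- ratio_regression(0.4 - 2 * ratio, ratio)
  expect_equal(exact$slope, -2)
  expect_equal(exact$intercept, 0.4)
  expect_equal(exact$r2, 1)
  expect_equal(exact$df, c(1, 20))
  flat <- ratio_regression(c(0, 1, 0), c(0, 1, 2))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_error(ratio_regression(c(1, 2, 3), rep(2, 3)), "constant")
})

test_that("model comparison attaches weights that sum to one and a best form", {
  cov <- model_grid_covariates()
  set.seed(77)
  ser <- sim_ricker_series(c(r_max = 0.4, k0 = 0.12, k_f = 0.015), "palm",
                           cov, n0 = 0.05, noise_sd = 0.02)
  fits <- compare_growth_models(ser, cov)
  expect_named(fits, c("constant", "palm", "soi", "palm_soi"))
  w <- vapply(fits, `[[`, numeric(1), "akaike_weight")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(attr(fits, "best") %in% names(fits))
  expect_true(all(is.finite(vapply(fits, `[[`, numeric(1), "pred_r2"))))
})
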