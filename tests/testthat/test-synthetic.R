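test_that("covariate generation honours its degenerate limits", {
  sc <- synthetic_scenario(seed = 1)
  # steepness -> infinity: step function at the midpoint
  sc_step <- synthetic_scenario(
    palm_decline = list(start = 40, end = 1, midpoint_ce = 1350,
                        steepness = 1e6), seed = 1)
  cov <- gen_covariates(sc_step)
  expect_true(all(cov$palm[cov$time_ce < 1350] == 40))
  expect_true(all(cov$palm[cov$time_ce > 1350] == 1))
  # no AR noise: SOI exactly linear
  sc_lin <- synthetic_scenario(
    soi_trend = list(intercept = -0.4, slope_per_century = 0.08, ar1 = 0,
                     innovation_sd = 0), seed = 1)
  cov2 <- gen_covariates(sc_lin)
  expect_equal(cov2$soi, -0.4 + 0.08 * (cov2$time_ce - 800) / 100,
               tolerance = 1e-12)
  # palm bounds respected
  cov3 <- gen_covariates(sc)
  expect_true(all(cov3$palm >= 1 & cov3$palm <= 40))
})

test_that("the AR(1) climate noise has the requested autocorrelation", {
  sc <- synthetic_scenario(
    horizon_ce = c(0, 9999), step = 1,
    soi_trend = list(intercept = 0, slope_per_century = 0, ar1 = 0.6,
                     innovation_sd = 0.1), seed = 8)
  cov <- gen_covariates(sc)
  rho <- acf(cov$soi, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(rho, 0.6, tolerance = 0.05)
})

test_that("population generation is a seeded Ricker iteration", {
  # constant covariates and n0 = K: equilibrium stays flat
  sc_flat <- synthetic_scenario(
    true_params = list(r_max = 0.4, k0 = 500), k_form = "constant",
    n0 = 500, obs_noise_sd = 0, seed = 3)
  pop <- gen_population(sc_flat)
  expect_true(all(pop$true$n == 500))
  expect_equal(pop$observed$n, pop$true$n)   # noise-free observation
  # declining palm-driven K: boom then bust
  sc <- synthetic_scenario(obs_noise_sd = 0, seed = 3)
  pop2 <- gen_population(sc)
  peak <- which.max(pop2$true$n)
  expect_gt(peak, 3)
  expect_lt(peak, nrow(pop2$true) - 3)
  expect_gt(pop2$true$n[peak] / pop2$true$n[1], 2)
  expect_gt(pop2$true$n[peak] / pop2$true$n[nrow(pop2$true)], 2)
  # direct iteration oracle
  cov <- pop2$covariates
  n <- numeric(nrow(cov)); n[1] <- pop2$true$n[1]
  for (j in 2:length(n)) {
    K <- 60 + 16.5 * cov$palm[j - 1]
    n[j] <- n[j - 1] * exp(0.4 * (1 - n[j - 1] / K))
  }
  expect_equal(pop2$true$n, n, tolerance = 1e-12)
})

test_that("generated dates follow the population and the site model", {
  # constant population: calendar-age draws are uniform (chi-square GOF)
  sc <- synthetic_scenario(
    true_params = list(r_max = 0.4, k0 = 500), k_form = "constant",
    n0 = 500, obs_noise_sd = 0, n_dates = 10000, n_sites = 5,
    date_error_range = c(1, 2), seed = 5)
  cv <- identity_curve(lo = -100, hi = 1500, sigma = 0)
  dates <- gen_dates(sc, curve = cv)
  # ages ~ cal BP + tiny noise; horizon 800-1790 CE = 160-1150 BP
  breaks <- seq(160, 1150, length.out = 11)
  counts <- table(cut(pmin(pmax(dates$age_14c, 160), 1150), breaks))
  p <- suppressWarnings(chisq.test(as.numeric(counts))$p.value)
  expect_gt(p, 0.01)
  # degenerate site assignment
  sc1 <- synthetic_scenario(n_dates = 50, n_sites = 1, seed = 6)
  d1 <- gen_dates(sc1)
  expect_equal(length(unique(d1$site_id)), 1L)
  # byte-identical under identical seeds
  sc2 <- synthetic_scenario(seed = 9)
  expect_identical(gen_dates(sc2), gen_dates(sc2))
  cov_a <- gen_covariates(sc2)
  expect_identical(cov_a, gen_covariates(sc2))
})

test_that("an exponentially growing population is recovered from the SPD log-slope", {
  curve <- synthetic_calibration_curve()
  r_true <- 0.2
  slopes <- numeric(5)
  for (i in 1:5) {
    sc <- synthetic_scenario(true_params = list(r_max = r_true, k0 = 1e6),
                             k_form = "constant", n0 = 1, obs_noise_sd = 0,
                             n_dates = 400, n_sites = 250, seed = 200 + i)
    pop <- gen_population(sc)
    dates <- gen_dates(sc, pop$true, curve)
    spd <- suppressWarnings(build_spd(dates, curve)$spd)
    keep <- spd$year_ce >= 1050 & spd$year_ce <= 1700 & spd$value > 0
    slopes[i] <- unname(coef(lm(log(spd$value[keep]) ~ spd$year_ce[keep]))[2]) * 30
  }
  expect_lt(abs(mean(slopes) - r_true) / r_true, 0.15)
})

test_that("the full loop recovers the generating carrying-capacity form", {
  curve <- synthetic_calibration_curve()
  reps <- 50
  wins <- 0
  for (i in seq_len(reps)) {
    sc <- synthetic_scenario(seed = 300 + i)
    pop <- gen_population(sc)
    dates <- gen_dates(sc, pop$true, curve)
    spd <- suppressWarnings(build_spd(dates, curve)$spd)
    ser <- resample_interval(spd, step = 30, start_ce = 1100, end_ce = 1760)
    cov <- pop$covariates[pop$covariates$time_ce %in% ser$time_ce, ]
    fits <- compare_growth_models(ser, cov)
    wins <- wins + (attr(fits, "best") == sc$k_form)
  }
  expect_gte(wins / reps, 0.6)
})

test_that("fixture sets are written complete and round-trip", {
  dir <- withr::local_tempdir()
  sc <- synthetic_scenario(n_dates = 40, seed = 4)
  paths <- write_scenario_fixtures(sc, dir)
  expect_true(all(file.exists(unlist(paths))))
  curve <- read_calibration_curve(paths$curve)
  # the fixture stores 12 significant digits
  expect_equal(as.data.frame(curve),
               as.data.frame(synthetic_calibration_curve()),
               tolerance = 1e-9)
  dates <- read_radiocarbon_dates(paths$dates)
  expect_equal(nrow(dates), 40L)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$k_form, "palm")
  expect_equal(truth$true_params$r_max, 0.4)
})
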