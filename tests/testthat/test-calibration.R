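test_that("calibration-curve files are parsed, sorted and interpolable", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# synthetic curve", "200,300,8", "0,100,5", "100,180,5"), path)
  cv <- read_calibration_curve(path)
  expect_s3_class(cv, "cal_curve")
  expect_equal(cv$cal_bp, c(0, 100, 200))
  at <- curve_at(cv, 50)
  expect_equal(at$mu, 140)
  expect_equal(at$sigma, 5)
  # whitespace-delimited variant parses identically
  path2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("0 100 5", "100 180 5", "200 300 8"), path2)
  expect_equal(read_calibration_curve(path2), cv)
  expect_error(curve_at(cv, 250), "outside")
  bad <- withr::local_tempfile()
  writeLines(c("0,100,5", "oops"), bad)
  expect_error(read_calibration_curve(bad), "line 2")
  dup <- withr::local_tempfile()
  writeLines(c("0,100,5", "0,110,5", "10,120,5"), dup)
  expect_error(read_calibration_curve(dup), "duplicate")
})

test_that("curve mixing follows the mean/variance mixing formulas", {
  grid <- seq(0, 500, 10)
  terr <- calibration_curve(grid, rep(1000, length(grid)), rep(10, length(grid)))
  mar <- calibration_curve(grid, rep(1400, length(grid)), rep(10, length(grid)))
  # f = 0: terrestrial curve returned unchanged, bit-for-bit
  expect_identical(mix_curves(terr, mar, 0), terr)
  # f = 1 with the local reservoir correction -83 +/- 34
  m1 <- mix_curves(terr, mar, 1, delta_r = -83, delta_r_error = 34)
  expect_equal(unique(m1$mu_14c), 1400 - 83)
  expect_equal(unique(m1$sigma_curve), sqrt(10^2 + 34^2))
  # f = 0.5, no reservoir: hand-evaluated mixture
  m05 <- mix_curves(terr, mar, 0.5)
  expect_equal(unique(m05$mu_14c), 1200)
  expect_equal(unique(m05$sigma_curve), sqrt(50), tolerance = 1e-12)
  expect_error(mix_curves(terr, mar, 1.2), "\\[0, 1\\]")
})

test_that("calibration against an identity curve recovers Gaussian structure", {
  cv <- identity_curve()
  d <- calibrate(1000, 50, cv)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  expect_equal(d$cal_bp[which.max(d$density)], 1000)
  in2sig <- d$cal_bp >= 902 & d$cal_bp <= 1098
  expect_equal(sum(d$density[in2sig]), 0.95, tolerance = 0.005)
  expect_equal(median_cal_age(d), 1000)
})

test_that("a flat curve yields a uniform calibrated density", {
  grid <- seq(0, 400, 5)
  flat <- calibration_curve(grid, rep(1000, length(grid)), rep(0, length(grid)))
  d <- suppressWarnings(calibrate(1000, 50, flat))
  expect_equal(max(d$density) / min(d$density), 1, tolerance = 1e-12)
})

test_that("plateaus produce multimodal densities with mass ratio given by the oracle", {
  # two plateaus at 14C age 1000: 60 yr and 30 yr wide
  cv <- calibration_curve(
    cal_bp = c(900, 1000, 1060, 1130, 1200, 1230, 1300),
    mu_14c = c(0, 1000, 1000, 2000, 1000, 1000, 2000),
    sigma_curve = rep(0, 7))
  grid <- seq(900, 1300, 1)
  d <- calibrate(1000, 15, cv, grid = grid)
  ora <- oracle_calibrate(1000, 15, cv, grid)
  ora <- ora / sum(ora)
  expect_lt(max(abs(d$density - ora)), 1e-8)
  mass_a <- sum(d$density[d$cal_bp >= 990 & d$cal_bp <= 1070])
  mass_b <- sum(d$density[d$cal_bp >= 1190 & d$cal_bp <= 1240])
  ora_a <- sum(ora[grid >= 990 & grid <= 1070])
  ora_b <- sum(ora[grid >= 1190 & grid <= 1240])
  expect_equal(mass_a / mass_b, ora_a / ora_b, tolerance = 1e-9)
  expect_equal(mass_a / mass_b, 2, tolerance = 0.15)
})

test_that("every normalized calibrated density sums to one", {
  cv <- synthetic_calibration_curve()
  set.seed(21)
  ages <- runif(20, 300, 1200)
  errs <- runif(20, 15, 80)
  dens <- calibrate_matrix(ages, errs, cv)
  expect_true(all(abs(colSums(dens) - 1) < 1e-9))
})

test_that("uncalibration implements the stated noise model", {
  cv <- identity_curve(sigma = 0)
  # noise-free limit: exactly mu(theta)
  expect_equal(uncalibrate(1000, cv, error = 0), 1000)
  # determinism under a fixed seed
  a <- uncalibrate(c(500, 900), cv, error = 30, seed = 7)
  b <- uncalibrate(c(500, 900), cv, error = 30, seed = 7)
  expect_identical(a, b)
  # sample sd of many draws matches sqrt(error^2 + sigma_curve^2)
  cvs <- identity_curve(sigma = 20)
  draws <- uncalibrate(rep(800, 1e4), cvs, error = 30, seed = 99)
  expect_equal(sd(draws), sqrt(30^2 + 20^2), tolerance = 0.05)
  expect_error(uncalibrate(5000, cv, error = 10), "outside")
})

test_that("d13C end-member interpolation maps the diet range onto [0, 1]", {
  expect_equal(d13c_to_marine_fraction(c(-21, -12, -16.5)), c(0, 1, 0.5))
  expect_equal(d13c_to_marine_fraction(-25), 0)  # clamped
  expect_equal(d13c_to_marine_fraction(-10), 1)
})

test_that("date tables are validated and material-aware calibrated", {
  tab <- data.frame(lab_id = c("A", "B", "C"), site_id = "S1",
                    age_14c = c(600, 700, 800), error = c(30, 40, 30),
                    material = c("terrestrial", "marine", "mixed"),
                    marine_fraction = c(NA, NA, 0.4))
  dates <- radiocarbon_dates(tab)
  expect_equal(dates$marine_fraction, c(NA, 1, 0.4))
  grid <- seq(0, 2000, 5)
  terr <- calibration_curve(grid, grid, rep(5, length(grid)))
  mar <- calibration_curve(grid, grid + 400, rep(5, length(grid)))
  dens <- calibrate_dates(dates, terr, marine_curve = mar,
                          delta_r = -83, delta_r_error = 34)
  g <- attr(dens, "cal_bp")
  # terrestrial date peaks at its 14C age; pure-marine date at age - 400 + 83
  expect_equal(g[which.max(dens[, 1])], 600, tolerance = 2)
  expect_equal(g[which.max(dens[, 2])], 700 - 400 + 83, tolerance = 2)
  expect_error(calibrate_dates(dates, terr), "marine_curve")
  expect_error(radiocarbon_dates(transform(tab, marine_fraction = c(0.5, 1, 0.4))),
               "absent for terrestrial")
  expect_error(radiocarbon_dates(transform(tab, error = c(0, 40, 30))), "> 0")
})
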