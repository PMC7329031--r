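# Fixtures and independent oracles used across the suite. Everything is
# built in code; no files are read.

# Identity calibration curve: mu(theta) = theta, constant curve error.
identity_curve <- function(lo = 0, hi = 3000, by = 5, sigma = 0) {
  grid <- seq(lo, hi, by = by)
  calibration_curve(grid, grid, rep(sigma, length(grid)))
}

# Brute-force calibration oracle: evaluate the likelihood on a fine grid,
# normalize by trapezoid integration, and return the density at the annual
# grid points. Independent of calibrate(): no shared normalization code.
oracle_calibrate <- function(age_14c, error, curve, grid, fine_by = 0.02) {
  fine <- seq(min(curve$cal_bp), max(curve$cal_bp), by = fine_by)
  mu_f <- approx(curve$cal_bp, curve$mu_14c, xout = fine)$y
  sg_f <- approx(curve$cal_bp, curve$sigma_curve, xout = fine)$y
  lik_f <- dnorm(age_14c, mean = mu_f, sd = sqrt(error^2 + sg_f^2))
  total <- sum((lik_f[-1] + lik_f[-length(lik_f)]) / 2) * fine_by
  mu_g <- approx(curve$cal_bp, curve$mu_14c, xout = grid)$y
  sg_g <- approx(curve$cal_bp, curve$sigma_curve, xout = grid)$y
  dnorm(age_14c, mean = mu_g, sd = sqrt(error^2 + sg_g^2)) / total
}

# Random smooth wiggly calibration curve for oracle comparisons.
random_curve <- function() {
  grid <- seq(0, 2500, by = 5)
  slope <- runif(1, 0.9, 1.1)
  mu <- runif(1, -50, 50) + slope * grid +
    runif(1, 2, 15) * sin(2 * pi * grid / runif(1, 150, 500)) +
    runif(1, 1, 6) * sin(2 * pi * grid / runif(1, 60, 140) + runif(1, 0, 6))
  sigma <- runif(1, 4, 12) + runif(1, 0, 5) * sin(2 * pi * grid / 700)^2
  calibration_curve(grid, mu, sigma)
}

# Simulate a demographic series from the Ricker model with lognormal
# process noise on the growth rate (the data-generating mechanism used in
# the recovery and coverage studies).
sim_ricker_series <- function(theta, k_form, covariates, n0, noise_sd = 0) {
  times <- covariates$time_ce
  nT <- length(times)
  n <- numeric(nT)
  n[1] <- n0
  for (j in 2:nT) {
    K <- (if ("k0" %in% names(theta)) theta[["k0"]] else 0) +
      (if ("k_f" %in% names(theta)) theta[["k_f"]] * covariates$palm[j - 1] else 0) +
      (if ("k_c" %in% names(theta)) theta[["k_c"]] * covariates$soi[j - 1] else 0)
    eps <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    n[j] <- n[j - 1] * exp(theta[["r_max"]] * (1 - n[j - 1] / K) + eps)
  }
  demographic_series(times, n)
}

# Deterministic covariates on the 1100-1760 CE model grid (23 points):
# declining palm, rising SOI with a non-trend component so the two are
# distinguishable.
model_grid_covariates <- function() {
  times <- seq(1100, 1760, by = 30)
  data.frame(
    time_ce = times,
    palm = 40 - 39 * (times - 1100) / 660,
    soi = -0.4 + 0.8 * (times - 1100) / 660 + 0.15 * sin(times / 97)
  )
}
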