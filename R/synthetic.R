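## Synthetic-data generator: covariates, Ricker population trajectories and
## radiocarbon date tables with known ground truth, so every pipeline stage
## is testable by parameter recovery without external downloads.

#' Define a synthetic study scenario
#'
#' The default scenario mirrors the structure of the Rapa Nui record: a
#' millennium-long horizon at one 30-year generation per step, a palm-forest
#' pollen fraction declining logistically from 40% to 1%, an upward-trending
#' autocorrelated SOI-like climate index, and a boom-and-bust population
#' driven by a palm-linked carrying capacity.
#'
#' @param horizon_ce `c(first, last)` model time points (CE).
#' @param step Generation step in years (default 30).
#' @param true_params Named list/vector of generating parameters (`r_max`,
#'   `k0`, and `k_f`/`k_c` as required by `k_form`).
#' @param k_form Generating carrying-capacity form.
#' @param n0 Initial population (SPD units); defaults to `0.1 * K` at the
#'   horizon start.
#' @param palm_decline List `start`, `end` (%), `midpoint_ce`, `steepness`
#'   (per year) of the logistic pollen decline.
#' @param soi_trend List `intercept` (index value at the horizon start),
#'   `slope_per_century`, `ar1`, `innovation_sd` of the climate index.
#' @param obs_noise_sd Multiplicative lognormal observation noise on the
#'   population proxy (sd of log, default 0.05).
#' @param n_dates,n_sites Size of the generated radiocarbon record.
#' @param date_error_range Uniform range for 1-sigma date errors (years).
#' @param seed Base seed; all generator draws derive from it.
#' @return An object of class `syn_scenario`.
#' @export
synthetic_scenario <- function(horizon_ce = c(800, 1790),
                               step = 30,
                               true_params = list(r_max = 0.4, k0 = 60,
                                                  k_f = 16.5),
                               k_form = "palm",
                               n0 = NULL,
                               palm_decline = list(start = 40, end = 1,
                                                   midpoint_ce = 1350,
                                                   steepness = 0.012),
                               soi_trend = list(intercept = -0.4,
                                                slope_per_century = 0.08,
                                                ar1 = 0.6,
                                                innovation_sd = 0.08),
                               obs_noise_sd = 0.05,
                               n_dates = 244, n_sites = 95,
                               date_error_range = c(15, 30),
                               seed = 42) {
  stopifnot(palm_decline$start > palm_decline$end, palm_decline$end >= 0,
            n_dates >= 1, abs(soi_trend$ar1) < 1, step >= 1)
  sc <- list(horizon_ce = horizon_ce, step = step,
             true_params = as.list(true_params), k_form = k_form, n0 = n0,
             palm_decline = palm_decline, soi_trend = soi_trend,
             obs_noise_sd = obs_noise_sd, n_dates = n_dates,
             n_sites = n_sites, date_error_range = date_error_range,
             seed = seed)
  class(sc) <- "syn_scenario"
  sc
}

#' Generate synthetic covariate series
#'
#' Palm pollen % follows a logistic decline between the scenario endpoints;
#' the SOI-like index is a linear trend plus AR(1) noise. Deterministic
#' under the scenario seed.
#'
#' @param scenario A `syn_scenario`.
#' @param times Time grid (CE); defaults to the scenario's step grid.
#' @return Data frame `time_ce`, `palm`, `soi`.
#' @export
gen_covariates <- function(scenario, times = NULL) {
  if (is.null(times))
    times <- seq(scenario$horizon_ce[1L], scenario$horizon_ce[2L],
                 by = scenario$step)
  pd <- scenario$palm_decline
  palm <- pd$end + (pd$start - pd$end) /
    (1 + exp(pd$steepness * (times - pd$midpoint_ce)))
  st <- scenario$soi_trend
  trend <- st$intercept +
    st$slope_per_century * (times - times[1L]) / 100
  eps <- with_seed(child_seed(scenario$seed, 1L), {
    n <- length(times)
    e <- numeric(n)
    innov <- stats::rnorm(n, 0, st$innovation_sd)
    if (n > 0) {
      ## stationary AR(1) start
      e[1L] <- if (st$innovation_sd > 0)
        stats::rnorm(1, 0, st$innovation_sd / sqrt(1 - st$ar1^2)) else 0
      for (i in seq_len(n - 1L)) e[i + 1L] <- st$ar1 * e[i] + innov[i + 1L]
    }
    e
  })
  data.frame(time_ce = times, palm = palm, soi = trend + eps)
}

#' Generate the true (and observed) population trajectory
#'
#' Iterates the Ricker map with the scenario's true parameters and
#' covariate-driven carrying capacity; optional multiplicative lognormal
#' observation noise produces the observed series.
#'
#' @param scenario A `syn_scenario`.
#' @param covariates Output of [gen_covariates()] (regenerated if omitted).
#' @return A list: `true` and `observed` `demographic_series`, plus the
#'   covariates used.
#' @export
gen_population <- function(scenario, covariates = NULL) {
  if (is.null(covariates)) covariates <- gen_covariates(scenario)
  theta <- unlist(scenario$true_params)
  times <- covariates$time_ce
  K1 <- carrying_capacity_series(theta, covariates, times, scenario$k_form,
                                 lag = 1L)
  n0 <- scenario$n0 %||% (0.1 * K1[1L])
  true <- simulate_trajectory(theta, n0 = n0, covariates = covariates,
                              times = times, k_form = scenario$k_form)
  obs_n <- if (scenario$obs_noise_sd > 0) {
    with_seed(child_seed(scenario$seed, 2L),
              true$n * exp(stats::rnorm(nrow(true), 0, scenario$obs_noise_sd)))
  } else true$n
  list(true = demographic_series(true$time_ce, true$n),
       observed = demographic_series(true$time_ce, obs_n),
       covariates = covariates)
}

#' Generate a radiocarbon date table from a population trajectory
#'
#' Samples calendar years with probability proportional to the (annually
#' interpolated) true population, simulates a 14C measurement for each via
#' [uncalibrate()], draws 1-sigma errors uniformly from the scenario range,
#' and assigns sites by a symmetric Dirichlet-multinomial. Deterministic
#' under the scenario seed.
#'
#' @param scenario A `syn_scenario`.
#' @param true_series A `demographic_series` (defaults to
#'   [gen_population()] output).
#' @param curve A `cal_curve` covering the horizon (defaults to
#'   [synthetic_calibration_curve()]).
#' @return A `c14_dates` table.
#' @export
gen_dates <- function(scenario, true_series = NULL, curve = NULL) {
  if (is.null(true_series)) true_series <- gen_population(scenario)$true
  if (is.null(curve)) curve <- synthetic_calibration_curve()
  years_ce <- seq(min(true_series$time_ce), max(true_series$time_ce), by = 1)
  n_annual <- stats::approx(true_series$time_ce, true_series$n,
                            xout = years_ce)$y
  rng <- range(curve$cal_bp)
  if (min(ce_to_bp(years_ce)) < rng[1L] || max(ce_to_bp(years_ce)) > rng[2L])
    stop("scenario horizon outside calibration-curve support")
  with_seed(child_seed(scenario$seed, 3L), {
    yrs <- sample(years_ce, scenario$n_dates, replace = TRUE,
                  prob = n_annual / sum(n_annual))
    errs <- round(stats::runif(scenario$n_dates,
                               scenario$date_error_range[1L],
                               scenario$date_error_range[2L]))
    ages <- round(uncalibrate(ce_to_bp(yrs), curve, errs))
    site_w <- stats::rgamma(scenario$n_sites, shape = 1)
    sites <- sample(seq_len(scenario$n_sites), scenario$n_dates,
                    replace = TRUE, prob = site_w / sum(site_w))
    radiocarbon_dates(data.frame(
      lab_id = sprintf("SYN-%04d", seq_len(scenario$n_dates)),
      site_id = sprintf("S%03d", sites),
      age_14c = pmax(ages, 1),
      error = pmax(errs, 1),
      material = "terrestrial",
      stringsAsFactors = FALSE))
  })
}

#' Bundled synthetic calibration curve
#'
#' A smooth, monotone calendar-to-14C mapping with mild wiggles and a
#' slowly varying curve error, adequate for tests and simulations without
#' downloading a real curve file. It is synthetic: it reproduces the
#' *structure* of a real curve, not its values.
#'
#' @param cal_bp_range Grid range (cal BP), default `c(-60, 1500)`.
#' @param by Knot spacing in years (default 5).
#' @return A `cal_curve`.
#' @export
synthetic_calibration_curve <- function(cal_bp_range = c(-60, 1500), by = 5) {
  grid <- seq(cal_bp_range[1L], cal_bp_range[2L], by = by)
  mu <- 30 + 1.02 * grid +
    12 * sin(2 * pi * grid / 300) + 5 * sin(2 * pi * grid / 80 + 1)
  sigma <- 8 + 4 * sin(2 * pi * grid / 500)^2
  calibration_curve(grid, mu, sigma)
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits the calibration curve (3-column text), the radiocarbon date table
#' (CSV), the covariate series (CSV) and the generating truth (JSON) so a
#' complete, self-contained analysis can be run from files.
#'
#' @param scenario A `syn_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_scenario_fixtures <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curve <- synthetic_calibration_curve()
  pop <- gen_population(scenario)
  dates <- gen_dates(scenario, pop$true, curve)
  paths <- list(
    curve = file.path(dir, "synthetic_curve.14c"),
    dates = file.path(dir, "dates.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.json")
  )
  writeLines(
    c("# synthetic calibration curve: cal BP, 14C age BP, 1-sigma error",
      sprintf("%.12g,%.12g,%.12g", curve$cal_bp, curve$mu_14c,
              curve$sigma_curve)),
    paths$curve)
  utils::write.csv(as.data.frame(dates), paths$dates, row.names = FALSE)
  utils::write.csv(pop$covariates, paths$covariates, row.names = FALSE)
  jsonlite::write_json(
    list(true_params = scenario$true_params, k_form = scenario$k_form,
         n0 = scenario$n0 %||% pop$true$n[1L],
         horizon_ce = scenario$horizon_ce, step = scenario$step,
         seed = scenario$seed,
         true_trajectory = pop$true),
    paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}
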