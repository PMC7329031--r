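## Radiocarbon calibration: curve handling, single-date calibration,
## curve mixing for marine/mixed-diet samples, and "uncalibration"
## (simulating a 14C measurement for a known calendar year).

#' Construct a calibration curve object
#'
#' A calibration curve maps calendar age (cal BP) to conventional 14C age
#' with a 1-sigma curve error. Values between knots are obtained by linear
#' interpolation.
#'
#' @param cal_bp Strictly monotone grid of calendar years BP.
#' @param mu_14c 14C age (years BP) at each grid point.
#' @param sigma_curve 1-sigma curve error (years) at each grid point.
#' @return An object of class `cal_curve`: a data frame with columns
#'   `cal_bp`, `mu_14c`, `sigma_curve`, sorted ascending in `cal_bp`.
#' @export
calibration_curve <- function(cal_bp, mu_14c, sigma_curve) {
  if (length(cal_bp) != length(mu_14c) || length(cal_bp) != length(sigma_curve))
    stop("cal_bp, mu_14c and sigma_curve must have equal lengths")
  if (length(cal_bp) < 2L) stop("a calibration curve needs at least 2 knots")
  ord <- order(cal_bp)
  cal_bp <- as.numeric(cal_bp[ord])
  mu_14c <- as.numeric(mu_14c[ord])
  sigma_curve <- as.numeric(sigma_curve[ord])
  if (any(diff(cal_bp) <= 0))
    stop("calibration-curve grid must be strictly monotone in cal BP")
  if (any(sigma_curve < 0)) stop("sigma_curve must be >= 0")
  out <- data.frame(cal_bp = cal_bp, mu_14c = mu_14c, sigma_curve = sigma_curve)
  class(out) <- c("cal_curve", "data.frame")
  out
}

#' Read a calibration curve file
#'
#' Reads the standard 3+-column calibration-curve layout (cal BP, 14C age BP,
#' 1-sigma error), comma- or whitespace-delimited, with optional comment
#' header lines starting with `#`. Columns beyond the third are ignored.
#'
#' @param path Path to the curve file.
#' @return A [calibration_curve()] object sorted ascending in cal BP.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("no data rows in calibration curve file: ", path)
  parse_row <- function(i) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop(sprintf("malformed calibration-curve row at line %d of %s",
                   line_no[i], path), call. = FALSE)
    val <- suppressWarnings(as.numeric(tok[1:3]))
    if (anyNA(val))
      stop(sprintf("non-numeric calibration-curve row at line %d of %s",
                   line_no[i], path), call. = FALSE)
    val
  }
  m <- t(vapply(seq_along(lines), parse_row, numeric(3)))
  if (anyDuplicated(m[, 1L]))
    stop("duplicate cal BP values in calibration curve: ", path)
  calibration_curve(m[, 1L], m[, 2L], m[, 3L])
}

#' Evaluate a calibration curve at arbitrary calendar ages
#'
#' Linear interpolation of the curve mean and error between knots. Queries
#' outside the curve support are an error.
#'
#' @param curve A `cal_curve`.
#' @param cal_bp Calendar ages (cal BP) to evaluate at.
#' @return A list with numeric vectors `mu` and `sigma`.
#' @export
curve_at <- function(curve, cal_bp) {
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1L] | cal_bp > rng[2L]))
    stop(sprintf("query outside calibration-curve support [%g, %g] cal BP",
                 rng[1L], rng[2L]))
  list(
    mu    = stats::approx(curve$cal_bp, curve$mu_14c, xout = cal_bp)$y,
    sigma = stats::approx(curve$cal_bp, curve$sigma_curve, xout = cal_bp)$y
  )
}

#' Mix terrestrial and marine calibration curves
#'
#' Builds the calibration curve for a sample whose carbon is a mixture of
#' terrestrial and marine sources. On the common annual grid,
#' `mu = (1 - f) * mu_terr + f * (mu_mar + delta_r)` and
#' `sigma^2 = (1 - f)^2 sigma_terr^2 + f^2 (sigma_mar^2 + delta_r_error^2)`,
#' where `f` is the marine-carbon fraction and `delta_r` a local marine
#' reservoir correction.
#'
#' @param terrestrial,marine `cal_curve` objects.
#' @param fraction Marine-carbon fraction in `[0, 1]`.
#' @param delta_r Local reservoir offset (years), e.g. `-83`.
#' @param delta_r_error 1-sigma error of the reservoir offset (years).
#' @return A `cal_curve` on the common annual grid. With `fraction = 0` the
#'   terrestrial curve is returned unchanged.
#' @export
mix_curves <- function(terrestrial, marine, fraction,
                       delta_r = 0, delta_r_error = 0) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (delta_r_error < 0) stop("delta_r_error must be >= 0")
  if (fraction == 0 && delta_r == 0 && delta_r_error == 0) return(terrestrial)
  lo <- max(min(terrestrial$cal_bp), min(marine$cal_bp))
  hi <- min(max(terrestrial$cal_bp), max(marine$cal_bp))
  if (lo >= hi) stop("terrestrial and marine curves share no grid overlap")
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  te <- curve_at(terrestrial, grid)
  ma <- curve_at(marine, grid)
  f <- fraction
  mu <- (1 - f) * te$mu + f * (ma$mu + delta_r)
  sg <- sqrt((1 - f)^2 * te$sigma^2 + f^2 * (ma$sigma^2 + delta_r_error^2))
  calibration_curve(grid, mu, sg)
}

#' Calibrate a radiocarbon determination
#'
#' The calibrated density on an annual calendar grid is proportional to the
#' Gaussian likelihood of the measured 14C age given the curve:
#' `dnorm(age_14c, mu(theta), sqrt(error^2 + sigma_curve(theta)^2))`,
#' normalized to unit mass over the grid.
#'
#' @param age_14c Measured 14C age (years BP).
#' @param error 1-sigma measurement error (years), `> 0`.
#' @param curve A `cal_curve` covering the region of non-negligible
#'   likelihood.
#' @param grid Optional annual cal BP grid; defaults to the full annual span
#'   of the curve.
#' @param normalize Normalize the density to sum to 1 (default `TRUE`).
#' @param edge_tol If the unnormalized likelihood at either grid edge exceeds
#'   `edge_tol` times its maximum, a warning flags possible truncation
#'   (default `1e-3`, about 4.4 sigma).
#' @return An object of class `cal_density`: data frame with columns
#'   `cal_bp` and `density` (probability mass per year).
#' @export
calibrate <- function(age_14c, error, curve, grid = NULL, normalize = TRUE,
                      edge_tol = 1e-3) {
  if (error <= 0) stop("error must be > 0")
  if (age_14c <= 0) stop("age_14c must be > 0")
  m <- calibrate_matrix(age_14c, error, curve, grid = grid,
                        normalize = normalize, edge_tol = edge_tol)
  out <- data.frame(cal_bp = attr(m, "cal_bp"), density = as.numeric(m))
  attr(out, "normalized") <- normalize
  class(out) <- c("cal_density", "data.frame")
  out
}

## Vectorized calibration of many dates against one curve: returns a
## grid x n_dates matrix of (optionally normalized) densities, with the
## cal BP grid as an attribute. This is the workhorse for SPDs and the
## Monte-Carlo null test.
calibrate_matrix <- function(ages, errors, curve, grid = NULL,
                             normalize = TRUE, edge_tol = 1e-3) {
  if (is.null(grid)) {
    grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  }
  cv <- curve_at(curve, grid)
  n <- length(ages)
  dens <- matrix(0, nrow = length(grid), ncol = n)
  for (j in seq_len(n)) {
    sd_tot <- sqrt(errors[j]^2 + cv$sigma^2)
    lik <- stats::dnorm(ages[j], mean = cv$mu, sd = sd_tot)
    mx <- max(lik)
    if (mx == 0)
      stop(sprintf("date %g +/- %g has no likelihood mass on the curve grid",
                   ages[j], errors[j]))
    if (!is.null(edge_tol) &&
        (lik[1L] > edge_tol * mx || lik[length(lik)] > edge_tol * mx))
      warning(sprintf(
        "likelihood of date %g +/- %g may be truncated at the grid edge",
        ages[j], errors[j]))
    dens[, j] <- if (normalize) lik / sum(lik) else lik
  }
  attr(dens, "cal_bp") <- grid
  dens
}

#' Median calibrated age
#'
#' @param density A `cal_density` (or a numeric density vector with a
#'   matching `cal_bp` vector).
#' @param cal_bp Grid, required when `density` is a bare vector.
#' @return Median calendar age (cal BP) of the calibrated density.
#' @export
median_cal_age <- function(density, cal_bp = NULL) {
  if (inherits(density, "cal_density")) {
    cal_bp <- density$cal_bp
    density <- density$density
  }
  p <- cumsum(density) / sum(density)
  cal_bp[which(p >= 0.5)[1L]]
}

#' Simulate a 14C measurement for a known calendar year
#'
#' The inverse of calibration, used by the Monte-Carlo null model and the
#' synthetic-date generator: returns
#' `mu(theta) + N(0, sigma_curve(theta)) + N(0, error)`.
#'
#' @param cal_bp Calendar year(s), cal BP, within curve support.
#' @param curve A `cal_curve`.
#' @param error 1-sigma measurement error(s), recycled against `cal_bp`.
#' @param seed Optional integer seed; fixed seeds give identical draws.
#' @return Numeric vector of simulated 14C ages (years BP).
#' @export
uncalibrate <- function(cal_bp, curve, error, seed = NULL) {
  cv <- curve_at(curve, cal_bp)
  n <- length(cal_bp)
  error <- rep_len(error, n)
  with_seed(seed, cv$mu + stats::rnorm(n, 0, cv$sigma) + stats::rnorm(n, 0, error))
}

#' Marine-diet fraction from a stable-carbon-isotope value
#'
#' Linear end-member interpolation of the marine-carbon fraction from a
#' collagen delta-13C value. Defaults: fully terrestrial diet at -21 per mil,
#' fully marine at -12 per mil; results are clamped to `[0, 1]`.
#'
#' @param d13c delta-13C values (per mil).
#' @param terrestrial_endmember,marine_endmember End-member delta-13C values.
#' @return Marine fractions in `[0, 1]`.
#' @export
d13c_to_marine_fraction <- function(d13c, terrestrial_endmember = -21,
                                    marine_endmember = -12) {
  f <- (d13c - terrestrial_endmember) / (marine_endmember - terrestrial_endmember)
  pmin(pmax(f, 0), 1)
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: %d knots, %g-%g cal BP\n",
              nrow(x), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

#' @export
print.cal_density <- function(x, ...) {
  med <- median_cal_age(x)
  cat(sprintf("Calibrated density on %d annual grid points; median %g cal BP (%g CE)\n",
              nrow(x), med, bp_to_ce(med)))
  invisible(x)
}
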