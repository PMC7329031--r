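## Summed probability distributions: site binning, summation, smoothing,
## and resampling to the demographic model grid.

#' Aggregate same-site dates into bins
#'
#' Corrects the overrepresentation of well-dated sites: within each site,
#' dates whose median calibrated ages cluster within `bin_width` years
#' (single-linkage) share a bin, and each date is down-weighted by its bin
#' size so every bin contributes unit mass to the SPD.
#'
#' @param dates A `c14_dates` table.
#' @param densities Matrix from [calibrate_dates()] (columns match rows of
#'   `dates`).
#' @param bin_width Clustering cutoff in years (default 50).
#' @return A data frame with columns `lab_id`, `site_id`, `median_bp`,
#'   `bin` (site-qualified bin label) and `weight` (`1 / bin size`). Per
#'   site, weights sum to the number of bins in that site.
#' @export
aggregate_site_bins <- function(dates, densities, bin_width = 50) {
  n <- nrow(dates)
  if (n == 0L)
    return(data.frame(lab_id = character(), site_id = character(),
                      median_bp = numeric(), bin = character(),
                      weight = numeric()))
  grid <- attr(densities, "cal_bp")
  med <- vapply(seq_len(n), function(j) median_cal_age(densities[, j], grid),
                numeric(1))
  bin <- character(n)
  for (s in unique(dates$site_id)) {
    idx <- which(dates$site_id == s)
    if (length(idx) == 1L) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(med[idx]), method = "single")
      cl <- stats::cutree(hc, h = bin_width)
    }
    bin[idx] <- paste(s, cl, sep = "_")
  }
  weight <- 1 / as.numeric(table(bin)[bin])
  data.frame(lab_id = dates$lab_id, site_id = dates$site_id,
             median_bp = med, bin = bin, weight = weight,
             stringsAsFactors = FALSE)
}

#' Construct an SPD series
#'
#' @param year_ce Contiguous annual calendar grid (CE).
#' @param value Non-negative summed density per year.
#' @param normalized,smoothed,window Metadata flags carried as attributes.
#' @param n_bins Number of bins contributing (total SPD mass before
#'   smoothing).
#' @return An object of class `spd_series` (data frame `year_ce`, `value`).
#' @export
spd_series <- function(year_ce, value, normalized = TRUE, smoothed = FALSE,
                       window = NA_real_, n_bins = NA_real_) {
  if (length(year_ce) != length(value)) stop("grid/value length mismatch")
  if (any(diff(year_ce) != 1)) stop("SPD grid must be annual and contiguous")
  if (any(value < -1e-12)) stop("SPD values must be >= 0")
  out <- data.frame(year_ce = year_ce, value = pmax(value, 0))
  attr(out, "normalized") <- normalized
  attr(out, "smoothed") <- smoothed
  attr(out, "window") <- window
  attr(out, "n_bins") <- n_bins
  class(out) <- c("spd_series", "data.frame")
  out
}

#' Sum weighted calibrated densities into an SPD
#'
#' Per calendar year, the SPD is the weight-weighted sum of the calibrated
#' densities; with normalized densities and bin weights from
#' [aggregate_site_bins()], the total SPD mass equals the number of bins.
#'
#' @param densities Matrix from [calibrate_dates()].
#' @param weights Per-date weights (default all 1).
#' @param year_range_ce Optional `c(min, max)` CE window for the output
#'   grid; defaults to the full density grid.
#' @return An `spd_series` on an ascending CE annual grid.
#' @export
sum_spd <- function(densities, weights = NULL, year_range_ce = NULL) {
  grid_bp <- attr(densities, "cal_bp")
  if (is.null(weights)) weights <- rep(1, ncol(densities))
  if (length(weights) != ncol(densities))
    stop("one weight per calibrated density required")
  total <- as.numeric(densities %*% weights)
  year_ce <- bp_to_ce(grid_bp)     # descending BP grid -> ascending CE
  ord <- order(year_ce)
  year_ce <- year_ce[ord]
  total <- total[ord]
  if (!is.null(year_range_ce)) {
    keep <- year_ce >= year_range_ce[1L] & year_ce <= year_range_ce[2L]
    year_ce <- year_ce[keep]
    total <- total[keep]
  }
  spd_series(year_ce, total, normalized = TRUE, smoothed = FALSE,
             n_bins = sum(weights))
}

#' Rolling-mean smoothing of an SPD
#'
#' Centred moving average of width `window` years; at the series edges the
#' window shrinks (truncated mean) so the series length is preserved.
#'
#' @param spd An `spd_series` (or any annual data frame `year_ce`, `value`).
#' @param window Window width in years (default 100).
#' @return The smoothed `spd_series`.
#' @export
rolling_smooth <- function(spd, window = 100) {
  n <- nrow(spd)
  if (window < 1 || window > n)
    stop("window must be in [1, series length]")
  half <- floor(window / 2)
  v <- spd$value
  ## truncated centred mean via cumulative sums
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  spd_series(spd$year_ce, sm, normalized = attr(spd, "normalized"),
             smoothed = TRUE, window = window, n_bins = attr(spd, "n_bins"))
}

#' Resample an SPD to the demographic model grid
#'
#' Sections the annual SPD into fixed intervals (default 30 years, a
#' generation) and takes the mean over each interval `(t - step, t]` as the
#' population proxy at `t`, suppressing high-frequency noise.
#'
#' @param spd A smoothed `spd_series`.
#' @param step Interval length in years (default 30).
#' @param start_ce First time point (CE); the first interval may be
#'   truncated at the series start.
#' @param end_ce Last time point (CE); defaults to the last full step.
#' @return A `demographic_series` (data frame `time_ce`, `n`); intervals
#'   with zero SPD mass are flagged via an `NA`-free error because the
#'   downstream log transform requires `n > 0`.
#' @export
resample_interval <- function(spd, step = 30, start_ce = 890, end_ce = NULL) {
  if (is.null(end_ce))
    end_ce <- start_ce + step * floor((max(spd$year_ce) - start_ce) / step)
  times <- seq(start_ce, end_ce, by = step)
  n <- vapply(times, function(t) {
    keep <- spd$year_ce > (t - step) & spd$year_ce <= t
    if (!any(keep)) return(NA_real_)
    mean(spd$value[keep])
  }, numeric(1))
  if (anyNA(n)) stop("resampling interval outside SPD coverage")
  if (any(n <= 0))
    stop(sprintf("zero SPD mass in interval(s) ending %s; log transform would fail",
                 paste(times[n <= 0], collapse = ", ")))
  demographic_series(times, n)
}

#' Build the full SPD population proxy from a date table
#'
#' Convenience wrapper running the observed-data pipeline: calibrate (per
#' material), drop modern entries, bin same-site dates, sum, and smooth.
#'
#' @inheritParams calibrate_dates
#' @param bin_width Site-bin clustering cutoff (years, default 50).
#' @param smooth_window Rolling-mean window (years, default 100).
#' @param modern_threshold Minimum retained 14C age (years BP).
#' @param year_range_ce Optional CE window for the SPD grid.
#' @return A list: `spd` (smoothed `spd_series`), `spd_raw` (unsmoothed),
#'   `bins` (binning table), `dates` (retained dates).
#' @export
build_spd <- function(dates, curve, marine_curve = NULL,
                      delta_r = 0, delta_r_error = 0,
                      bin_width = 50, smooth_window = 100,
                      modern_threshold = 125, year_range_ce = NULL) {
  dates <- filter_modern_dates(dates, modern_threshold)
  if (nrow(dates) == 0L) stop("no dates left after the modern-age filter")
  dens <- calibrate_dates(dates, curve, marine_curve = marine_curve,
                          delta_r = delta_r, delta_r_error = delta_r_error)
  bins <- aggregate_site_bins(dates, dens, bin_width = bin_width)
  raw <- sum_spd(dens, weights = bins$weight, year_range_ce = year_range_ce)
  smooth <- rolling_smooth(raw, window = smooth_window)
  list(spd = smooth, spd_raw = raw, bins = bins, dates = dates)
}

#' @export
print.spd_series <- function(x, ...) {
  cat(sprintf("SPD series: %d-%d CE (%d yr), mass %.4f%s%s\n",
              min(x$year_ce), max(x$year_ce), nrow(x), sum(x$value),
              if (isTRUE(attr(x, "smoothed")))
                sprintf(", smoothed (window %g yr)", attr(x, "window")) else "",
              if (!is.na(attr(x, "n_bins")))
                sprintf(", %g bins", attr(x, "n_bins")) else ""))
  invisible(x)
}

#' Write / read an SPD series as CSV (`year_ce,value`)
#'
#' @param spd An `spd_series`.
#' @param path Output CSV path.
#' @export
write_spd_csv <- function(spd, path) {
  utils::write.csv(as.data.frame(spd)[, c("year_ce", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spd_csv
#' @export
read_spd_csv <- function(path) {
  x <- utils::read.csv(path)
  spd_series(x$year_ce, x$value)
}
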