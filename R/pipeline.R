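## End-to-end pipeline: configuration, covariate alignment, the full
## SPD -> growth-model -> vegetation analysis, and artifact reporting.

#' Align raw covariate records to the demographic model grid
#'
#' Pollen percentages are linearly interpolated to the model time points;
#' the (annual) SOI reconstruction is averaged within each step interval
#' `(t - step, t]`, truncated at the record start.
#'
#' @param pollen Data frame `time_ce`, `palm_pct` (irregular sample times).
#' @param soi Data frame `time_ce`, `soi` (annual or finer).
#' @param times Model time grid (CE).
#' @param step Interval length for the SOI mean (years, default 30).
#' @return Data frame `time_ce`, `palm`, `soi` on the model grid.
#' @export
prepare_covariates <- function(pollen, soi, times, step = 30) {
  palm <- stats::approx(pollen$time_ce, pollen$palm_pct, xout = times,
                        rule = 2)$y
  soi_step <- vapply(times, function(t) {
    keep <- soi$time_ce > (t - step) & soi$time_ce <= t
    if (!any(keep)) keep <- which.min(abs(soi$time_ce - t))
    mean(soi$soi[keep])
  }, numeric(1))
  data.frame(time_ce = times, palm = palm, soi = soi_step)
}

#' Assemble and validate a pipeline configuration
#'
#' Defaults encode the standard analysis: 50-yr site bins, 100-yr rolling
#' mean, 30-yr model steps over 1100-1760 CE, a linear null model with 1000
#' simulations at the 95% level, the four carrying-capacity forms, and
#' 10000-draw 95% trajectory bands.
#'
#' @param curve Terrestrial calibration curve: a `cal_curve` or file path.
#' @param dates Radiocarbon dates: a `c14_dates` table or CSV path.
#' @param pollen Pollen series: data frame `time_ce`, `palm_pct` or CSV
#'   path.
#' @param soi SOI series: data frame `time_ce`, `soi` or CSV path.
#' @param marine_curve Optional marine `cal_curve` or path.
#' @param delta_r,delta_r_error Marine reservoir correction (years).
#' @param out_dir Output directory for artifacts (`NULL`: no files).
#' @param bin_width,smooth_window,step SPD options (years).
#' @param window_ce Analysis window `c(first, last)` CE for model fitting.
#' @param null_model,n_sim,envelope_level Null-test options (`n_sim = 0`
#'   skips the test).
#' @param k_forms Carrying-capacity forms to compare.
#' @param ci_iter,ci_level Trajectory-band options.
#' @param seed Integer seed for all stochastic stages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(curve, dates, pollen, soi,
                            marine_curve = NULL,
                            delta_r = 0, delta_r_error = 0,
                            out_dir = NULL,
                            bin_width = 50, smooth_window = 100, step = 30,
                            window_ce = c(1100, 1760),
                            null_model = "linear", n_sim = 1000,
                            envelope_level = 95,
                            k_forms = c("constant", "palm", "soi", "palm_soi"),
                            ci_iter = 10000, ci_level = 0.95,
                            seed = 1L) {
  if (is.character(curve)) curve <- read_calibration_curve(curve)
  if (is.character(marine_curve))
    marine_curve <- read_calibration_curve(marine_curve)
  if (is.character(dates)) dates <- read_radiocarbon_dates(dates)
  dates <- radiocarbon_dates(dates)
  if (is.character(pollen)) pollen <- utils::read.csv(pollen)
  if (is.character(soi)) soi <- utils::read.csv(soi)
  bad <- setdiff(k_forms, c("constant", "palm", "soi", "palm_soi"))
  if (length(bad))
    stop("unknown k_form(s) in configuration: ", paste(bad, collapse = ", "))
  stopifnot(bin_width >= 1, smooth_window >= 1, step >= 1,
            length(window_ce) == 2L, window_ce[1L] < window_ce[2L],
            ci_level > 0, ci_level < 1, envelope_level > 0,
            envelope_level < 100, ci_iter >= 2)
  cfg <- list(curve = curve, marine_curve = marine_curve, dates = dates,
              pollen = pollen, soi = soi,
              delta_r = delta_r, delta_r_error = delta_r_error,
              out_dir = out_dir, bin_width = bin_width,
              smooth_window = smooth_window, step = step,
              window_ce = window_ce, null_model = null_model,
              n_sim = n_sim, envelope_level = envelope_level,
              k_forms = k_forms, ci_iter = ci_iter, ci_level = ci_level,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML holds flat keys matching the [pipeline_config()] arguments, with
#' `curve`, `dates`, `pollen` and `soi` given as file paths (resolved
#' relative to the YAML file). Arguments supplied in `...` override the
#' file, which is how a command-line `--seed` is applied.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("curve", "marine_curve", "dates", "pollen", "soi")) {
    if (!is.null(y[[k]]) && is.character(y[[k]]) &&
        !file.exists(y[[k]]) && file.exists(file.path(base, y[[k]])))
      y[[k]] <- file.path(base, y[[k]])
  }
  if (!is.null(y$window_ce)) y$window_ce <- as.numeric(unlist(y$window_ce))
  if (!is.null(y$k_forms)) y$k_forms <- as.character(unlist(y$k_forms))
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

#' Run the full palaeodemographic analysis
#'
#' Executes, in order: SPD construction (calibration, binning, summation,
#' smoothing), optional Monte-Carlo null test, resampling to the model
#' grid, covariate alignment, fitting of all configured carrying-capacity
#' forms with Akaike weights and prediction coefficients, trajectory
#' confidence bands, population/resource ratio regressions, and the pollen
#' regression candidate set. When `out_dir` is set, writes CSV/JSON
#' artifacts plus a run log carrying the seed and configuration hash.
#'
#' @param config A `pipeline_config`.
#' @return A report list with elements `spd`, `series`, `covariates`,
#'   `fits`, `bands`, `ratio_palm`, `ratio_soi`, `vegetation`, `null_test`
#'   and `files` (written paths, if any).
#' @export
run_full_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config")) stop("config must be a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  spd_res <- stage("spd", build_spd(
    cfg$dates, cfg$curve, marine_curve = cfg$marine_curve,
    delta_r = cfg$delta_r, delta_r_error = cfg$delta_r_error,
    bin_width = cfg$bin_width, smooth_window = cfg$smooth_window))

  null_test <- NULL
  if (cfg$n_sim > 0) {
    null_test <- stage("nulltest", mc_null_envelope(
      cfg$dates, cfg$curve, marine_curve = cfg$marine_curve,
      delta_r = cfg$delta_r, delta_r_error = cfg$delta_r_error,
      null_model = cfg$null_model, n_sim = cfg$n_sim,
      level = cfg$envelope_level, bin_width = cfg$bin_width,
      smooth_window = cfg$smooth_window,
      seed = child_seed(cfg$seed, 11L)))
  }

  series <- stage("resample", resample_interval(
    spd_res$spd, step = cfg$step, start_ce = cfg$window_ce[1L],
    end_ce = cfg$window_ce[2L]))
  covariates <- stage("covariates", prepare_covariates(
    cfg$pollen, cfg$soi, times = series$time_ce, step = cfg$step))

  fits <- stage("fit", compare_growth_models(
    series, covariates, forms = cfg$k_forms))

  ## a model whose parameter uncertainty mostly implies K <= 0 cannot be
  ## banded; record the diagnostic instead of aborting the other models
  bands <- stage("simulate", lapply(fits, function(f)
    tryCatch(
      trajectory_ci(f, n0 = series$n[1L], covariates = covariates,
                    times = series$time_ce, n_iter = cfg$ci_iter,
                    level = cfg$ci_level,
                    seed = child_seed(cfg$seed, 13L)),
      error = function(e) {
        warning(sprintf("no trajectory band for k_form '%s': %s",
                        f$k_form, conditionMessage(e)), call. = FALSE)
        structure(list(error = conditionMessage(e)), class = "band_failure")
      })))

  r_obs <- per_capita_growth(series)
  gf <- growth_frame(series, covariates, lag = 1)
  ratio_palm <- stage("ratio_palm",
                      ratio_regression(gf$R, gf$n_prev / gf$palm_prev))
  ratio_soi <- stage("ratio_soi",
                     ratio_regression(gf$R, gf$n_prev / gf$soi_prev))

  veg_table <- stage("vegfit_align", align_pollen_predictors(
    cfg$pollen[cfg$pollen$time_ce >= min(spd_res$spd$year_ce) + cfg$step &
                 cfg$pollen$time_ce <= max(spd_res$spd$year_ce), ,
               drop = FALSE],
    spd_res$spd, cfg$soi, window = cfg$step))
  vegetation <- stage("vegfit", compare_vegetation_models(veg_table))

  report <- list(spd = spd_res$spd, spd_raw = spd_res$spd_raw,
                 bins = spd_res$bins, series = series,
                 covariates = covariates, fits = fits, bands = bands,
                 r_obs = r_obs, ratio_palm = ratio_palm,
                 ratio_soi = ratio_soi, vegetation = vegetation,
                 null_test = null_test, config = cfg, files = list())
  if (!is.null(cfg$out_dir)) report$files <- write_report(report, cfg$out_dir)
  report
}

fit_summary <- function(f) {
  list(k_form = f$k_form, coefficients = as.list(f$coefficients),
       covariance = unname(apply(f$vcov, 1L, as.list)),
       rss = f$rss, n_obs = f$n_obs, aicc = f$aicc,
       akaike_weight = f$akaike_weight %||% NA_real_,
       pred_r2 = f$pred_r2 %||% NA_real_)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  files <- list(
    spd = file.path(out_dir, "spd.csv"),
    series = file.path(out_dir, "demographic_series.csv"),
    fits = file.path(out_dir, "model_fits.json"),
    trajectories = file.path(out_dir, "trajectories.csv"),
    vegetation = file.path(out_dir, "vegetation_fits.json"),
    run_log = file.path(out_dir, "run_log.json")
  )
  write_spd_csv(report$spd, files$spd)
  utils::write.csv(as.data.frame(report$series), files$series,
                   row.names = FALSE)
  jsonlite::write_json(
    list(models = lapply(report$fits, fit_summary),
         best = attr(report$fits, "best"),
         ratio_palm = report$ratio_palm, ratio_soi = report$ratio_soi),
    files$fits, auto_unbox = TRUE, digits = 12)
  traj <- do.call(rbind, lapply(names(report$bands), function(nm) {
    if (inherits(report$bands[[nm]], "band_failure")) return(NULL)
    b <- as.data.frame(report$bands[[nm]])
    b$k_form <- nm
    b
  }))
  utils::write.csv(traj, files$trajectories, row.names = FALSE)
  jsonlite::write_json(
    list(models = lapply(report$vegetation, function(v)
      list(terms = v$included_terms, params = v$params, rss = v$rss,
           r2 = v$r2, aicc = v$aicc,
           akaike_weight = v$akaike_weight %||% NA_real_)),
      best = attr(report$vegetation, "best")),
    files$vegetation, auto_unbox = TRUE, digits = 12)
  if (!is.null(report$null_test)) {
    files$null_csv <- file.path(out_dir, "null_test.csv")
    files$null_json <- file.path(out_dir, "null_test.json")
    write_null_test(report$null_test, files$null_csv, files$null_json)
  }
  ## provenance: the seed plus a hash of the numeric configuration
  cfg_txt <- tempfile()
  on.exit(unlink(cfg_txt), add = TRUE)
  dput(cfg[c("bin_width", "smooth_window", "step", "window_ce",
             "null_model", "n_sim", "envelope_level", "k_forms",
             "ci_iter", "ci_level", "seed")], file = cfg_txt)
  jsonlite::write_json(
    list(package = "carbondem",
         version = as.character(utils::packageVersion("carbondem")),
         seed = cfg$seed,
         config_hash = unname(tools::md5sum(cfg_txt)),
         n_dates = nrow(cfg$dates),
         n_bins = unname(attr(report$spd, "n_bins"))),
    files$run_log, auto_unbox = TRUE, digits = 12)
  files
}
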