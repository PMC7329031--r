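## Ricker-logistic population dynamics with covariate-driven carrying
## capacity: realized growth rates, multistart NLS fitting, AICc model
## selection, forward simulation and parameter-uncertainty bands.

#' Construct a demographic series
#'
#' @param time_ce Strictly increasing calendar years at a constant step.
#' @param n Positive population proxy values (SPD units).
#' @return An object of class `demographic_series` (data frame `time_ce`,
#'   `n`).
#' @export
demographic_series <- function(time_ce, n) {
  if (length(time_ce) != length(n)) stop("time/value length mismatch")
  d <- diff(time_ce)
  if (length(d) && (any(d <= 0) || any(d != d[1L])))
    stop("time_ce must be strictly increasing with a constant step")
  if (any(n <= 0)) stop("all population values must be > 0")
  out <- data.frame(time_ce = time_ce, n = n)
  class(out) <- c("demographic_series", "data.frame")
  out
}

#' Realized per-capita growth rates
#'
#' `R_t = ln(n_t) - ln(n_{t-1})` per time step (one generation).
#'
#' @param series A `demographic_series` (or positive numeric vector).
#' @return Numeric vector of length `length(n) - 1`.
#' @export
per_capita_growth <- function(series) {
  n <- if (is.data.frame(series)) series$n else series
  if (any(n <= 0)) stop("per-capita growth requires n > 0")
  diff(log(n))
}

k_form_coefs <- function(k_form, intercept = TRUE) {
  base <- switch(k_form,
    constant = "k0",
    palm     = c("k0", "k_f"),
    soi      = c("k0", "k_c"),
    palm_soi = c("k0", "k_f", "k_c"),
    stop("unknown k_form: ", k_form))
  if (!intercept && k_form != "constant") base <- setdiff(base, "k0")
  base
}

#' Carrying capacity as a linear function of covariates
#'
#' `K = k0 + k_f * palm + k_c * soi`; coefficients absent from the model
#' form are zero.
#'
#' @param params Named vector/list with `k0` and optionally `k_f`, `k_c`.
#' @param palm,soi Covariate values (palm pollen %, SOI index).
#' @param check Error when any K is non-positive (default `TRUE`).
#' @return Numeric vector of carrying capacities.
#' @export
carrying_capacity <- function(params, palm = 0, soi = 0, check = TRUE) {
  p <- as.list(params)
  k <- (p$k0 %||% 0) + (p$k_f %||% 0) * palm + (p$k_c %||% 0) * soi
  if (check && any(k <= 0))
    stop("carrying capacity K <= 0: invalid parameter region")
  k
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' One Ricker step
#'
#' `n_next = n_prev * exp(r_max * (1 - n_prev / K))`.
#'
#' @param r_max Maximum per-capita reproductive rate (per step).
#' @param n_prev Current population (`> 0`).
#' @param K Carrying capacity (`> 0`).
#' @return Next population value.
#' @export
ricker_step <- function(r_max, n_prev, K) {
  if (any(n_prev <= 0)) stop("n_prev must be > 0")
  if (any(K <= 0)) stop("K must be > 0")
  n_prev * exp(r_max * (1 - n_prev / K))
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = n ln(rss / n) + 2k + 2k(k + 1) / (n - k - 1)` for Gaussian
#' errors, up to an additive constant shared by all models; `k` counts every
#' estimated quantity including the error variance.
#'
#' @param n_obs Number of observations.
#' @param n_params Total parameter count `k` (error variance included).
#' @param rss Residual sum of squares.
#' @return AICc value.
#' @export
aicc <- function(n_obs, n_params, rss) {
  if (n_obs <= n_params + 1)
    stop("AICc undefined: n_obs must exceed n_params + 1")
  n_obs * log(rss / n_obs) + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

#' Akaike weights
#'
#' `w_i` proportional to `exp(-(AICc_i - min AICc) / 2)`, normalized to sum
#' to 1.
#'
#' @param aicc_values Numeric vector of at least two AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L) stop("need at least two models to weight")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

## Assemble the regression frame: R_t with lagged N and covariates.
growth_frame <- function(series, covariates = NULL, lag = 1) {
  if (lag < 1) stop("lag must be >= 1 step")
  nT <- nrow(series)
  i <- seq(lag + 1L, nT)
  R <- log(series$n[i]) - log(series$n[i - 1L])
  df <- data.frame(time_ce = series$time_ce[i], R = R,
                   n_prev = series$n[i - 1L])
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    m <- match(series$time_ce, cv$time_ce)
    if (anyNA(m)) stop("covariates must cover every series time point")
    if ("palm" %in% names(cv)) df$palm_prev <- cv$palm[m][i - lag]
    if ("soi" %in% names(cv))  df$soi_prev  <- cv$soi[m][i - lag]
  }
  df
}

ricker_predict <- function(theta, df, k_form) {
  K <- (if ("k0" %in% names(theta)) theta[["k0"]] else 0) +
    (if ("k_f" %in% names(theta)) theta[["k_f"]] * df$palm_prev else 0) +
    (if ("k_c" %in% names(theta)) theta[["k_c"]] * df$soi_prev else 0)
  if (length(K) == 1L) K <- rep(K, nrow(df))
  list(K = K, R = theta[["r_max"]] * (1 - df$n_prev / K))
}

## Penalized RSS: carrying capacities at or below `k_floor` are clamped for
## prediction and the objective is inflated smoothly with the excursion, so
## derivative-free searches stay stable near the invalid region.
growth_objective <- function(theta, df, k_form, k_floor) {
  K <- (if ("k0" %in% names(theta)) theta[["k0"]] else 0) +
    (if ("k_f" %in% names(theta)) theta[["k_f"]] * df$palm_prev else 0) +
    (if ("k_c" %in% names(theta)) theta[["k_c"]] * df$soi_prev else 0)
  bad <- pmax(k_floor - K, 0)
  bad_r <- max(1e-6 - theta[["r_max"]], 0)
  Kc <- pmax(K, k_floor)
  pred <- max(theta[["r_max"]], 1e-6) * (1 - df$n_prev / Kc)
  rss <- sum((df$R - pred)^2)
  rss * (1 + sum(bad) / k_floor + bad_r / 1e-6) +
    sum((bad / k_floor)^2) + (bad_r / 1e-6)^2
}

#' Fit a Ricker growth model by multistart nonlinear least squares
#'
#' Minimizes the squared residuals of the realized per-capita growth rates
#' around `r_max * (1 - N_{t-1} / K(F_{t-lag}, C_{t-lag}))` where the
#' carrying capacity is constant (`k_form = "constant"`) or linear in palm
#' pollen (`"palm"`), SOI (`"soi"`) or both (`"palm_soi"`). Optimization
#' uses a deterministic Latin-hypercube multistart (plus a closed-form
#' start from the linearized constant-K model) refined by Nelder-Mead and
#' polished with Levenberg-Marquardt NLS.
#'
#' @param series A `demographic_series`.
#' @param covariates Data frame `time_ce`, `palm`, `soi` aligned to the
#'   series grid (required for covariate forms).
#' @param k_form One of `"constant"`, `"palm"`, `"soi"`, `"palm_soi"`.
#' @param lag Covariate/density lag in steps (default 1).
#' @param intercept Keep the baseline `k0` term in covariate forms
#'   (default `TRUE`); `FALSE` gives the pure-proportionality variant.
#' @param n_starts Number of Latin-hypercube starts (default 20).
#' @param r_max_range Search range for `r_max` (default `(0, 2]`).
#' @return An object of class `growth_fit`: coefficients, asymptotic
#'   covariance, `rss`, `n_obs`, `aicc`, the model frame, and convergence
#'   details.
#' @export
fit_growth_model <- function(series, covariates = NULL,
                             k_form = c("constant", "palm", "soi", "palm_soi"),
                             lag = 1, intercept = TRUE, n_starts = 20,
                             r_max_range = c(1e-3, 2)) {
  k_form <- match.arg(k_form)
  if (k_form != "constant" && is.null(covariates))
    stop("covariates required for k_form = ", k_form)
  df <- growth_frame(series, covariates, lag = lag)
  if (k_form %in% c("palm", "palm_soi") && is.null(df$palm_prev))
    stop("covariates must contain a 'palm' column for k_form = ", k_form)
  if (k_form %in% c("soi", "palm_soi") && is.null(df$soi_prev))
    stop("covariates must contain a 'soi' column for k_form = ", k_form)
  coefs <- c("r_max", k_form_coefs(k_form, intercept))
  p <- length(coefs)
  if (nrow(df) < p + 3L)
    stop(sprintf("too few growth-rate observations (%d) for %d parameters",
                 nrow(df), p))

  nmax <- max(series$n)
  k_floor <- 1e-6 * nmax

  ## parameter boxes for the Latin-hypercube starts
  span <- function(x) max(abs(x), 1e-12)
  lowers <- c(r_max = r_max_range[1L])
  uppers <- c(r_max = r_max_range[2L])
  if ("k0" %in% coefs) { lowers["k0"] <- 0.05 * nmax; uppers["k0"] <- 3 * nmax }
  if ("k_f" %in% coefs) {
    s <- 2 * nmax / span(df$palm_prev)
    lowers["k_f"] <- -s; uppers["k_f"] <- s
  }
  if ("k_c" %in% coefs) {
    s <- 2 * nmax / span(df$soi_prev)
    lowers["k_c"] <- -s; uppers["k_c"] <- s
  }
  lowers <- lowers[coefs]; uppers <- uppers[coefs]

  hyper <- with_seed(760L, lhs::randomLHS(n_starts, p))
  starts <- lapply(seq_len(n_starts), function(i) {
    th <- lowers + hyper[i, ] * (uppers - lowers)
    names(th) <- coefs
    th
  })

  ## closed-form start: R = a - b * N is the linearized constant-K model
  lin <- stats::lm(R ~ n_prev, data = df)
  a <- unname(stats::coef(lin)[1L]); b <- -unname(stats::coef(lin)[2L])
  r0 <- min(max(a, 0.05), r_max_range[2L])
  K0 <- if (b > 0 && a > 0) a / b else 1.5 * nmax
  smart <- stats::setNames(numeric(p), coefs)
  smart["r_max"] <- r0
  if ("k0" %in% coefs) smart["k0"] <- if (intercept && p > 2) K0 / 2 else K0
  if ("k_f" %in% coefs)
    smart["k_f"] <- (K0 / ifelse(intercept, 2, 1)) / mean(df$palm_prev)
  if ("k_c" %in% coefs) smart["k_c"] <- 0
  starts <- c(list(smart), starts)

  ## screen all starts by raw objective value, then refine the best few
  obj0 <- vapply(starts, growth_objective, numeric(1), df = df,
                 k_form = k_form, k_floor = k_floor)
  refine <- starts[order(obj0)[seq_len(min(6L, length(starts)))]]
  fits <- lapply(refine, function(th) {
    stats::optim(th, growth_objective, df = df, k_form = k_form,
                 k_floor = k_floor, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[order(vals)[seq_len(min(3L, length(fits)))]]

  ## polish the best candidates with Levenberg-Marquardt on the raw model
  rhs <- c("r_max * (1 - n_prev / (",
           paste(c(if ("k0" %in% coefs) "k0",
                   if ("k_f" %in% coefs) "k_f * palm_prev",
                   if ("k_c" %in% coefs) "k_c * soi_prev"),
                 collapse = " + "),
           "))")
  form <- stats::as.formula(paste("R ~", paste(rhs, collapse = "")))
  polish <- function(th) {
    tryCatch(
      minpack.lm::nlsLM(form, data = df, start = as.list(th),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  }
  cands <- Filter(Negate(is.null), lapply(best, function(f) polish(f$par)))
  if (length(cands)) {
    rsss <- vapply(cands, function(m) sum(stats::resid(m)^2), numeric(1))
    ## a polished fit must respect the model constraints: r_max > 0
    ## (a maximum reproductive rate) and K > 0 at every data point
    ok <- vapply(cands, function(m) {
      th <- stats::coef(m)
      K <- ricker_predict(th, df, k_form)$K
      th[["r_max"]] > 0 && all(K > 0)
    }, logical(1))
    cands <- cands[ok]; rsss <- rsss[ok]
  }
  if (length(cands) == 0L) {
    ## fall back on the penalized optimum
    f <- best[[1L]]
    theta <- f$par
    K <- ricker_predict(theta, df, k_form)$K
    if (any(K <= 0) || theta[["r_max"]] <= 0)
      stop("growth-model fit did not converge to a valid region ",
           "(r_max > 0, K > 0); tried ", length(starts), " starts")
    pred <- theta[["r_max"]] * (1 - df$n_prev / K)
    rss <- sum((df$R - pred)^2)
    vc <- growth_vcov_numeric(theta, df, k_form, rss)
    fit_obj <- NULL
  } else {
    m <- cands[[which.min(rsss)]]
    theta <- stats::coef(m)
    rss <- sum(stats::resid(m)^2)
    vc <- tryCatch(stats::vcov(m),
                   error = function(e) growth_vcov_numeric(theta, df, k_form, rss))
    fit_obj <- m
  }

  n_obs <- nrow(df)
  k_tot <- p + 1L   # error variance counted
  out <- list(
    k_form = k_form, lag = lag, intercept = intercept,
    coefficients = theta, vcov = vc, rss = rss, n_obs = n_obs,
    n_params = p, aicc = aicc(n_obs, k_tot, rss),
    sigma = sqrt(rss / max(n_obs - p, 1L)),
    model_frame = df, nls = fit_obj
  )
  class(out) <- "growth_fit"
  out
}

## Asymptotic covariance from a finite-difference Jacobian when the NLS
## polish is unavailable: sigma^2 (J'J)^-1.
growth_vcov_numeric <- function(theta, df, k_form, rss) {
  p <- length(theta)
  f0 <- ricker_predict(theta, df, k_form)$R
  J <- matrix(0, nrow = nrow(df), ncol = p)
  for (j in seq_len(p)) {
    h <- max(abs(theta[j]), 1) * 1e-6
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (ricker_predict(th, df, k_form)$R - f0) / h
  }
  s2 <- rss / max(nrow(df) - p, 1L)
  vc <- tryCatch(s2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(names(theta), names(theta))
  vc
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Ricker growth model (K form: %s), %d obs\n", x$k_form, x$n_obs))
  print(round(x$coefficients, 6))
  cat(sprintf("rss = %.6g, AICc = %.4f\n", x$rss, x$aicc))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
vcov.growth_fit <- function(object, ...) object$vcov

#' Deterministic forward simulation of a fitted model
#'
#' Iterates [ricker_step()] from `n0` along the covariate series: the step
#' into time `t` uses the carrying capacity evaluated at `t - lag`.
#'
#' @param fit A `growth_fit`, or a named parameter vector (then `k_form`
#'   must be given).
#' @param n0 Initial population value (at the first time point).
#' @param covariates Data frame `time_ce`, `palm`, `soi` spanning the
#'   horizon (may be `NULL` for constant K).
#' @param times Simulation time grid; defaults to the covariate grid.
#' @param k_form,lag Used when `fit` is a bare parameter vector.
#' @param on_invalid_k `"error"` (default) or `"truncate"`: clamp K at a
#'   small positive floor with a warning.
#' @return A data frame `time_ce`, `n`.
#' @export
simulate_trajectory <- function(fit, n0, covariates = NULL, times = NULL,
                                k_form = NULL, lag = 1,
                                on_invalid_k = c("error", "truncate")) {
  on_invalid_k <- match.arg(on_invalid_k)
  if (inherits(fit, "growth_fit")) {
    theta <- fit$coefficients; k_form <- fit$k_form; lag <- fit$lag
  } else {
    theta <- fit
    if (is.null(k_form)) stop("k_form required with bare parameters")
  }
  if (is.null(times)) {
    if (is.null(covariates)) stop("either times or covariates required")
    times <- covariates$time_ce
  }
  nT <- length(times)
  Kt <- carrying_capacity_series(theta, covariates, times, k_form, lag,
                                 on_invalid_k)
  n <- numeric(nT)
  n[1L] <- n0
  r <- theta[["r_max"]]
  for (i in seq(2L, nT)) n[i] <- n[i - 1L] * exp(r * (1 - n[i - 1L] / Kt[i]))
  data.frame(time_ce = times, n = n)
}

## K at every step (indexed by the *target* time; entry i is used for the
## step into times[i], evaluated at times[i - lag]).
carrying_capacity_series <- function(theta, covariates, times, k_form, lag,
                                     on_invalid_k = "error") {
  nT <- length(times)
  if (k_form == "constant") {
    K <- rep(theta[["k0"]], nT)
  } else {
    cv <- as.data.frame(covariates)
    m <- match(times, cv$time_ce)
    if (anyNA(m)) stop("covariates must cover every simulation time point")
    idx <- pmax(seq_len(nT) - lag, 1L)
    palm <- if ("palm" %in% names(cv)) cv$palm[m][idx] else 0
    soi  <- if ("soi" %in% names(cv)) cv$soi[m][idx] else 0
    K <- carrying_capacity(theta, palm = palm, soi = soi, check = FALSE)
  }
  if (any(K <= 0)) {
    if (on_invalid_k == "error")
      stop("carrying capacity K <= 0 along the simulation horizon")
    warning("carrying capacity truncated at a positive floor")
    K <- pmax(K, 1e-6 * max(K, 1))
  }
  K
}

#' Coefficient of prediction
#'
#' `R^2 = 1 - sum((Y - X)^2) / sum((X - mean(X))^2)` with `X` observed and
#' `Y` predicted; negative values mean the model predicts worse than the
#' observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (`observed` not
#'   constant).
#' @return The coefficient of prediction.
#' @export
prediction_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("observed and predicted must be equal-length, length >= 2")
  ss <- sum((observed - mean(observed))^2)
  if (ss == 0) stop("observed series is constant")
  1 - sum((predicted - observed)^2) / ss
}

#' Trajectory confidence band by parameter resampling
#'
#' Draws parameter vectors from the asymptotic multivariate-normal
#' distribution of the estimates, simulates each trajectory forward from
#' `n0`, and returns per-time percentile bounds. Draws implying a
#' non-positive carrying capacity anywhere on the horizon are rejected.
#'
#' @param fit A `growth_fit`.
#' @param n0 Initial population value.
#' @param covariates Covariate frame spanning the horizon (see
#'   [simulate_trajectory()]).
#' @param times Simulation grid (defaults to the covariate grid).
#' @param n_iter Number of parameter draws (default 10000).
#' @param level Band coverage level (default 0.95).
#' @param seed Optional integer seed.
#' @return An object of class `trajectory_band`: data frame `time_ce`,
#'   `point`, `lo`, `hi`, with the rejection count as attribute
#'   `n_rejected`.
#' @export
trajectory_ci <- function(fit, n0, covariates = NULL, times = NULL,
                          n_iter = 10000, level = 0.95, seed = NULL) {
  if (is.null(times)) {
    if (is.null(covariates)) stop("either times or covariates required")
    times <- covariates$time_ce
  }
  theta <- fit$coefficients
  vc <- fit$vcov
  if (anyNA(vc)) stop("fit covariance unavailable; cannot resample")
  draws <- with_seed(seed, MASS::mvrnorm(n_iter, mu = theta, Sigma = vc))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_iter)
  colnames(draws) <- names(theta)

  nT <- length(times)
  ## K matrix: n_iter x nT, linear in the drawn coefficients
  idx <- pmax(seq_len(nT) - fit$lag, 1L)
  if (fit$k_form == "constant") {
    Kmat <- matrix(draws[, "k0"], nrow = n_iter, ncol = nT)
  } else {
    cv <- as.data.frame(covariates)
    m <- match(times, cv$time_ce)
    if (anyNA(m)) stop("covariates must cover every simulation time point")
    palm <- if ("palm" %in% colnames(cv)) cv$palm[m][idx] else rep(0, nT)
    soi  <- if ("soi" %in% colnames(cv)) cv$soi[m][idx] else rep(0, nT)
    Kmat <- matrix(if ("k0" %in% colnames(draws)) draws[, "k0"] else 0,
                   nrow = n_iter, ncol = nT)
    if ("k_f" %in% colnames(draws))
      Kmat <- Kmat + tcrossprod(draws[, "k_f"], palm)
    if ("k_c" %in% colnames(draws))
      Kmat <- Kmat + tcrossprod(draws[, "k_c"], soi)
  }
  valid <- rowSums(Kmat <= 0) == 0L
  n_rej <- sum(!valid)
  if (n_rej > n_iter / 2)
    stop(sprintf("%.0f%% of parameter draws imply K <= 0; consider reparameterization",
                 100 * n_rej / n_iter))
  draws <- draws[valid, , drop = FALSE]
  Kmat <- Kmat[valid, , drop = FALSE]

  r <- draws[, "r_max"]
  N <- matrix(NA_real_, nrow = nrow(draws), ncol = nT)
  N[, 1L] <- n0
  for (i in seq(2L, nT))
    N[, i] <- N[, i - 1L] * exp(r * (1 - N[, i - 1L] / Kmat[, i]))

  alpha <- (1 - level) / 2
  lo <- apply(N, 2L, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(N, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
  point <- simulate_trajectory(fit, n0, covariates, times)$n
  out <- data.frame(time_ce = times, point = point, lo = lo, hi = hi)
  attr(out, "n_rejected") <- n_rej
  attr(out, "level") <- level
  class(out) <- c("trajectory_band", "data.frame")
  out
}

#' Growth rate against a population/resource ratio
#'
#' Ordinary least squares of the realized growth rates on the ratio of
#' population to a resource covariate (e.g. `N / palm` or `N / SOI`), the
#' linearization implied by a proportional carrying capacity.
#'
#' @param r_obs Realized per-capita growth rates.
#' @param ratio Matching ratio vector (length >= 3, not constant).
#' @return A list: `slope`, `intercept`, `f_stat`, `df` (`c(1, n - 2)`),
#'   `r2`, `p_value`.
#' @export
ratio_regression <- function(r_obs, ratio) {
  if (length(r_obs) != length(ratio) || length(r_obs) < 3L)
    stop("r_obs and ratio must be equal-length, length >= 3")
  if (stats::sd(ratio) == 0) stop("ratio vector is constant")
  fit <- stats::lm(r_obs ~ ratio)
  ## suppress the perfect-fit warning: noiseless lines are legitimate input
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       f_stat = unname(fs[1L]),
       df = unname(fs[2:3]),
       r2 = sm$r.squared,
       p_value = unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)))
}

#' Fit and compare the four carrying-capacity forms
#'
#' Fits `constant`, `palm`, `soi` and `palm_soi` models, attaches Akaike
#' weights and forward-simulation prediction coefficients.
#'
#' @inheritParams fit_growth_model
#' @param forms Model forms to compare.
#' @return A list of `growth_fit` objects (named by form), each with
#'   `akaike_weight` and `pred_r2` filled in; attribute `best` names the
#'   lowest-AICc form.
#' @export
compare_growth_models <- function(series, covariates = NULL,
                                  forms = c("constant", "palm", "soi", "palm_soi"),
                                  lag = 1, intercept = TRUE, n_starts = 20) {
  fits <- lapply(forms, function(f)
    fit_growth_model(series, covariates, k_form = f, lag = lag,
                     intercept = intercept, n_starts = n_starts))
  names(fits) <- forms
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  for (i in seq_along(fits)) {
    fits[[i]]$akaike_weight <- w[[i]]
    traj <- simulate_trajectory(fits[[i]], n0 = series$n[1L],
                                covariates = covariates,
                                times = series$time_ce)
    fits[[i]]$pred_r2 <- prediction_r2(series$n, traj$n)
  }
  attr(fits, "best") <- forms[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]
  fits
}
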