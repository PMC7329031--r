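## Vegetation regression: palm pollen % explained by population pressure
## (SPD), climate (SOI) and their interaction, with AICc selection over the
## hierarchy-respecting term subsets.

#' Build the pollen regression table
#'
#' For each pollen sample time `t`, the response is the palm pollen
#' percentage and the predictors are `N` = mean SPD over the previous 30
#' years `(t - window, t]` and `C` = mean SOI over the same interval.
#' Sample times outside the SPD/SOI coverage are dropped with a message.
#'
#' @param pollen Data frame `time_ce`, `palm_pct`.
#' @param spd An annual `spd_series`.
#' @param soi Data frame `time_ce`, `soi` (annual or finer).
#' @param window Averaging window in years (default 30).
#' @return Data frame `time_ce`, `palm_pct`, `n`, `soi`.
#' @export
align_pollen_predictors <- function(pollen, spd, soi, window = 30) {
  mean_over <- function(t, times, values) {
    keep <- times > (t - window) & times <= t
    if (!any(keep)) return(NA_real_)
    mean(values[keep])
  }
  n <- vapply(pollen$time_ce, mean_over, numeric(1),
              times = spd$year_ce, values = spd$value)
  c_ <- vapply(pollen$time_ce, mean_over, numeric(1),
               times = soi$time_ce, values = soi$soi)
  drop <- is.na(n) | is.na(c_)
  if (any(drop))
    message(sprintf("dropped %d pollen sample(s) outside SPD/SOI coverage: %s",
                    sum(drop), paste(pollen$time_ce[drop], collapse = ", ")))
  data.frame(time_ce = pollen$time_ce[!drop],
             palm_pct = pollen$palm_pct[!drop],
             n = n[!drop], soi = c_[!drop])
}

#' Fit a palm-pollen regression
#'
#' Ordinary least squares of pollen % on a subset of
#' `{N, C, N x C}` (population, climate, interaction):
#' `F = alpha + beta N + gamma C + omega (N C) + eps`. The interaction is
#' only admitted when both main effects are present.
#'
#' @param table Output of [align_pollen_predictors()].
#' @param terms Character subset of `c("N", "C", "NxC")`; empty fits the
#'   intercept-only model.
#' @param standardize Z-score the pollen response before fitting (default
#'   `FALSE`: raw percentages).
#' @return An object of class `veg_fit`: `params` (alpha, beta, gamma,
#'   omega, sigma_eps), `included_terms`, `rss`, `r2`, `aicc`, `n_obs`, and
#'   the underlying `lm` fit.
#' @export
fit_vegetation <- function(table, terms = c("N", "C", "NxC"),
                           standardize = FALSE) {
  terms <- unique(terms)
  bad <- setdiff(terms, c("N", "C", "NxC"))
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  if ("NxC" %in% terms && !all(c("N", "C") %in% terms))
    stop("interaction requires both main effects (model hierarchy)")
  df <- data.frame(F_resp = table$palm_pct, N = table$n, C = table$soi)
  if (standardize) df$F_resp <- as.numeric(scale(df$F_resp))
  p_terms <- length(terms)
  if (nrow(df) < p_terms + 2L)
    stop("too few rows for the requested term subset")
  rhs <- c("1", if ("N" %in% terms) "N", if ("C" %in% terms) "C",
           if ("NxC" %in% terms) "N:C")
  fm <- stats::as.formula(paste("F_resp ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fm, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # noiseless recovery is legitimate
  rss <- sum(stats::resid(fit)^2)
  n <- nrow(df)
  params <- list(
    alpha = unname(cf["(Intercept)"]),
    beta  = if ("N" %in% names(cf)) unname(cf["N"]) else 0,
    gamma = if ("C" %in% names(cf)) unname(cf["C"]) else 0,
    omega = if ("N:C" %in% names(cf)) unname(cf["N:C"]) else 0,
    sigma_eps = sqrt(rss / max(n - length(cf), 1L))
  )
  out <- list(
    params = params, included_terms = terms, rss = rss,
    r2 = sm$r.squared, n_obs = n,
    aicc = aicc(n, length(cf) + 1L, rss),  # + error variance
    se = sm$coefficients[, "Std. Error"],
    lm = fit
  )
  class(out) <- "veg_fit"
  out
}

#' Compare nested pollen-regression candidates by AICc
#'
#' Fits the candidate set `{N}`, `{C}`, `{N, C}`, `{N, C, N x C}` and
#' attaches Akaike weights.
#'
#' @inheritParams fit_vegetation
#' @return Named list of `veg_fit`s with `akaike_weight` filled in;
#'   attribute `best` names the lowest-AICc candidate.
#' @export
compare_vegetation_models <- function(table, standardize = FALSE) {
  cand <- list(N = "N", C = "C", `N+C` = c("N", "C"),
               `N+C+NxC` = c("N", "C", "NxC"))
  fits <- lapply(cand, fit_vegetation, table = table,
                 standardize = standardize)
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  for (i in seq_along(fits)) fits[[i]]$akaike_weight <- w[[i]]
  attr(fits, "best") <- names(cand)[which.min(
    vapply(fits, `[[`, numeric(1), "aicc"))]
  fits
}

#' @export
print.veg_fit <- function(x, ...) {
  cat(sprintf("Pollen regression (terms: %s), %d obs\n",
              paste(x$included_terms, collapse = ", "), x$n_obs))
  cat(sprintf("  alpha=%.4g beta=%.4g gamma=%.4g omega=%.4g\n",
              x$params$alpha, x$params$beta, x$params$gamma, x$params$omega))
  cat(sprintf("  r2 = %.4f, AICc = %.4f\n", x$r2, x$aicc))
  invisible(x)
}
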