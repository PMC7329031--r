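# carbondem

Palaeodemography from radiocarbon archives, with population-dynamic model
testing. `carbondem` is for archaeologists and palaeoecologists who have a
table of radiocarbon dates and want to go beyond drawing a summed
probability distribution (SPD): it asks whether the reconstructed
population trajectory is better explained by a fixed carrying capacity or
by one driven by vegetation and climate covariates, with formal model
selection and uncertainty. The motivating case is Rapa Nui (Easter
Island) — palm-forest collapse, a drift toward La Niña-like drought
conditions, and pre-contact demographic contractions — but nothing in the
package is island-specific.

## The model

The population proxy is the SPD: each date is calibrated
(`density ∝ N(age_14c; μ(θ), √(error² + σ_curve(θ)²))`, normalized),
same-site dates within 50 years are binned and down-weighted, the sum is
smoothed with a 100-yr rolling mean and averaged over 30-yr generations.
A Monte-Carlo envelope test (1000 simulated date sets drawn from a fitted
linear or exponential null, each "uncalibrated" and pushed through the
identical pipeline) separates genuine booms and busts from calibration
noise.

Growth dynamics use the Ricker (discrete logistic) model written on the
realized per-capita growth rate `R_t = ln N_t − ln N_{t−1}`:

    R_t = r_max · (1 − N_{t−1} / K(F_{t−1}, C_{t−1})),
    K   = k0 + k_f·F + k_c·C

with four carrying-capacity forms (constant, palm pollen `F`, SOI `C`,
both), fitted by multistart nonlinear least squares and compared with the
small-sample Akaike criterion
`AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)` and Akaike weights.
Predictive skill is the coefficient of prediction
`R² = 1 − Σ(Y−X)²/Σ(X−mean X)²` of the full forward-simulated trajectory;
95% bands come from 10 000 multivariate-normal parameter draws. A
companion regression explains pollen from population, climate and their
interaction, and a fully seeded synthetic generator (covariates →
population → dates) makes every stage testable by parameter recovery.

## Worked example

```r
library(carbondem)

sc    <- synthetic_scenario(seed = 42)        # documented default scenario
curve <- synthetic_calibration_curve()
pop   <- gen_population(sc)                   # true + observed trajectory
dates <- gen_dates(sc, pop$true, curve)       # 244 dates from 95 sites

spd <- build_spd(dates, curve)                # calibrate, bin, sum, smooth
spd$spd
#> SPD series: 450-2010 CE (1561 yr), mass 188.0000, smoothed (window 100 yr), 188 bins

ser  <- resample_interval(spd$spd, step = 30, start_ce = 1100, end_ce = 1760)
cov  <- pop$covariates[pop$covariates$time_ce %in% ser$time_ce, ]
fits <- compare_growth_models(ser, cov)

fits$palm
#> Ricker growth model (K form: palm), 22 obs
#>    r_max       k0      k_f
#> 0.026847 0.006436 0.002768
#> rss = 0.0757634, AICc = -114.4131

round(sapply(fits, `[[`, "akaike_weight"), 4)
#> constant     palm      soi palm_soi
#>   0.0001   0.7224   0.0074   0.2701

round(100 * sapply(fits, `[[`, "pred_r2"), 1)
#> constant     palm      soi palm_soi
#>     78.1     96.2     85.2     96.4
```

Reading this: the SPD carries 188 bins of mass from the 244 generated
dates; on the 1100–1760 CE window (22 growth-rate observations) the
palm-driven carrying-capacity model gets 72% of the Akaike weight and
forward-simulates 96% of the observed variance, against 78% for the
constant-K model — the generating model (`palm`) is correctly preferred.
The coefficients are in SPD units; their ratio `k0/k_f ≈ 2.3` pollen-%
(the pollen level at which the baseline matches the vegetation term) and
`r_max` per 30-yr generation are the interpretable scales.
`mc_null_envelope()` adds the boom/bust significance test, and
`run_full_pipeline(pipeline_config(...))` runs everything (SPD, null test,
four model fits, bands, ratio regressions, vegetation regressions) and
writes CSV/JSON artifacts.

## Layout

- `R/` — calibration (`calibration.R`, `dates.R`), SPD (`spd.R`), null
  test (`nulltest.R`), growth models (`growth.R`), vegetation regression
  (`vegetation.R`), synthetic generator (`synthetic.R`), pipeline/config
  (`pipeline.R`).
- `vignettes/carbondem-methods.Rmd` — the methods account: model
  assumptions, parameter meanings and defaults, numerical choices, what
  the synthetic generator does and does not emulate, limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
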