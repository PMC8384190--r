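# dielmetab

Stream metabolism estimation and dissolved-oxygen monitoring analysis for
high-frequency sensor records, built for the common question facing urban
stream monitoring: how do wastewater treatment plant (WWTP) effluent,
riparian shading and the choice of monitoring window shape what a DO
sensor — and a regulator reading it — sees?

`dielmetab` provides, as one tested pipeline:

- **Sensor QAQC** — automated surrogates for manual DO data cleaning:
  storm-clog removal, storm-disrupted-day removal, single-point despiking,
  3-point smoothing of noisy diel days, no-diel-signal screening, and
  multi-day drift (biofouling) detection, each leaving an auditable flag.
- **Daily metabolism** — the one-station diel-oxygen method. Each day's
  gross primary production (GPP), ecosystem respiration (ER) and gas
  exchange (K600) are estimated in a state-space model with both process
  and observation error:

  O_{i+1} = [ O_i (1 − k_i Δt/2) + (GPP/z) w_i + (ER/z) Δt
              + k_i Δt O̅_sat,i + ε_i ] / (1 + k_i Δt/2)

  with light fractions w_i from a clear-sky solar model, Garcia–Benson
  saturation O_sat(T), Schmidt-number scaling k_i = K600 (Sc_O2/600)^(−1/2),
  process noise ε_i and Gaussian observation error. Because the model is
  linear-Gaussian given the parameters, the latent states are marginalised
  exactly by a Kalman filter (compiled code) and MCMC runs over the five
  parameters only; a two-pass procedure pools K600 information across days
  into a site-level lognormal prior. Estimates are filtered by the standard
  usability rules (signs, 95% CIs excluding zero, Gelman–Rubin R̂ < 1.05,
  DO-fit RMSE).
- **Light, PIL and seasons** — modeled clear-sky PAR from solar position;
  the potential incident light (PIL) canopy-openness metric from leaf-on /
  leaf-off visible channel areas; a season classifier from leaf-out date
  and a 4 °C weekly-temperature persistence rule.
- **WWTP effect statistics** — paired-day GPP/ER amplification ratios
  (downstream/upstream), Kruskal–Wallis tests with the field's star
  convention, Pearson/OLS regressions, and bivariate "metabolic
  fingerprint" kernel densities.
- **Regulatory windows** — every 3/7/15/30-day monitoring window with up to
  3-day gaps, window means of daily means and minima, strict-inequality
  violation counts against the 6 mg/L (mean) and 5 mg/L (mean-minimum)
  chronic criteria, and single-day violation capture distributions.
- **Synthetic data** — a forward simulator with known daily parameters,
  realistic sensor artifacts (clogs, spikes, drift, noise bursts) and
  paired upstream/downstream network scenarios, so every stage is testable
  end to end without field data.

## Worked example

Simulate a day of diel DO, fit it, and read the estimate:

```r
library(dielmetab)

cfg <- sim_config("2017-06-01", "2017-06-01", depth = 0.3,
                  sigma_obs = 0.2, seed = 42)
truth <- true_day_params(as.Date("2017-06-01"), gpp = 5, er = -6, k600 = 8)
sim <- simulate_do_series(truth, cfg)

par <- modeled_par(sim$series$timestamp, cfg$latitude, cfg$longitude)$par
fit <- fit_day(as.Date("2017-06-01"), sim$series$do, sim$series$temp, par,
               depth = 0.3, dt_days = 15 / 1440,
               control = mcmc_control(burn_in = 500, saved = 500,
                                      thin = 10, seed = 7))
fit[, c("gpp", "gpp_lo", "gpp_hi", "er", "k600", "fit_rmse", "usable")]
#>        gpp  gpp_lo   gpp_hi        er     k600  fit_rmse usable
#> 1 4.576811 4.18465 5.112669 -5.553212 7.016548 0.2019795   TRUE
```

The posterior median GPP of 4.58 g O2 m^-2 d^-1 (95% CI 4.18–5.11) and ER
of −5.55 recover the simulated 5 and −6 within one day's noise; `usable`
confirms the estimate passes the sign, credible-interval, convergence and
fit-quality rules. `fit_site()` runs this for every day of a record with
the two-pass K600 prior; `run_pipeline()` chains simulation, QAQC,
fitting, amplification statistics and window analysis into one output
bundle (see `inst/scripts/run-pipeline.R` for a command-line entry point).

Published context is bundled for the cross-site analyses:

```r
tab <- wissahickon_annual_metabolism()
sites <- wissahickon_sites()
d <- sites$distance_km[match(tab$site, sites$site)]
pearson_r(d, tab$gpp)                     #> 0.01621237
ols_regression(tab$gpp, tab$er)$r_squared #> 0.9181442
```

GPP shows essentially no trend with distance along the stream (r ≈ 0.016),
while GPP and ER are tightly coupled across sites (R² ≈ 0.92) — light and
local reach conditions, not position in the network, organise metabolism.

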