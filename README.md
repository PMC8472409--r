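# panelkink

Panel kink-threshold regression by first-difference GMM, built around the
question of how body mass index (BMI) relates to weekly work hours in a
two-wave adult cohort. The package is for researchers studying nonlinear
health–productivity relationships in short panels: it estimates where the
BMI–hours slope changes and by how much, while removing individual fixed
effects and instrumenting BMI with childhood weight measures.

## The model

For individual *i* in period *t* ∈ {1, 2},

    y_it = β0 + x_it'β + α·q_it + δ·(q_it − γ)·1{q_it ≥ γ} + ω_i + ε_it

where `y` is weekly hours, `q` is BMI (kg/m²), `x` are time-varying
covariates, `ω_i` an individual fixed effect and `γ` the unknown threshold.
The kink term keeps the regression function continuous at `γ`: the BMI
slope is `α` below the threshold and `α + δ` above it. First-differencing
removes `ω_i`; four time-invariant childhood instruments (birth weight,
own/mother's/father's BMI at age 10) identify the endogenous BMI terms.
Estimation profiles a two-step GMM criterion over a trimmed grid of
candidate thresholds (default: 400 points between the 15th and 85th
percentiles of pooled BMI).

The package provides:

* `simulate_panel()` / `default_bcs_config()` — a synthetic two-period
  cohort generator matched to the study cohort's published moments, with
  endogenous BMI, childhood instruments and a kinked outcome response;
* `fit_panel_threshold()` — the first-difference GMM kink estimator with
  trimmed grid search, two-step weighting, analytic sandwich or pairs
  bootstrap standard errors and a J-statistic;
* `fit_pooled_ols()` / `fit_fixed_effects()` — the linear benchmarks;
* `instrument_diagnostics()`, `cragg_donald()`, `sargan_test()`,
  `stock_yogo_lookup()` — instrument strength and validity diagnostics;
* `run_analysis()` — the full desk-scale pipeline: sample filters with an
  audit, summary statistics, the three-estimator comparison by gender,
  trim-rate sensitivity, skill subgroups and SD-standardized effect sizes,
  written as JSON and text reports.

## Worked example

Simulate the female arm at its analysis sample size (n = 828, truth
α = 4.656, δ = −7.088, γ = 30.021) and fit the threshold model:

```r
library(panelkink)
cfg <- default_bcs_config("female", seed = 7)
sim <- simulate_panel(cfg)
fit <- fit_panel_threshold(sim$data, sim$instruments)
print(fit)
#> Panel kink-threshold model (first-difference GMM, two_step)
#>             estimate     se
#> (Intercept)   1.2092 0.3774
#> d_degree      2.7609 1.1122
#> d_famsize    -0.6742 0.2237
#> d_skill_ind   1.9125 1.1248
#> d_england     1.5373 2.0877
#> d_bmi         4.5797 0.3331
#> kink         -5.8795 3.6325
#> gamma        30.2632 2.4433
#> Regime slopes: below = 4.58  above = -1.3
#> J-statistic: 0.185 on 1 df (p = 0.667)
#> n = 828 individuals; converged: TRUE
```

Read: below the estimated threshold of about 30 kg/m² an extra BMI unit is
associated with ~4.6 more weekly hours (`d_bmi` = α̂); above it the slope
change `kink` (δ̂) turns the total effect negative (α̂ + δ̂ ≈ −1.3 hours per
BMI unit, the `above` regime slope). The J-statistic does not reject the
overidentifying restrictions. Instrument quality:

```r
instrument_diagnostics(sim$data, sim$instruments)
#> Instrument diagnostics (n = 828 individuals)
#>   first-stage R^2 (BMI levels on childhood instruments): 0.1585
#>   Cragg-Donald F (differenced first stage): 19.37  vs Stock-Yogo bias_5 critical value 16.85
#>   Sargan: stat = 7.334 on 3 df, p = 0.062
```

A caution that also shapes the real analysis: the threshold is weakly
identified by the differenced moment system at this sample size, so read
`fit$objective_profile` and the trim-rate sensitivity panel
(`trim_sensitivity()`) together with the point estimate. The methods
vignette (`vignettes/panel-kink-threshold.Rmd`) explains the model,
the generator's design and the estimator's limitations in detail.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates both cohort arms at their analysis sample sizes, executes the
full pipeline (filters, three estimators per gender, diagnostics, trim
sensitivity, subgroups, effect sizes) and writes the acceptance JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
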