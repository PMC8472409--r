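---
title: "Panel kink-threshold regression by first-difference GMM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel kink-threshold regression by first-difference GMM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkink)
```

## The model

`panelkink` estimates how body mass index (BMI) relates to weekly work
hours when the relationship is allowed to change slope at an unknown BMI
value. For individual $i$ in period $t \in \{1, 2\}$,

$$
y_{it} = \beta_0 + x_{it}'\beta + \alpha\, q_{it}
       + \delta\,(q_{it} - \gamma)\,1\{q_{it} \ge \gamma\}
       + \omega_i + \varepsilon_{it},
$$

where $y$ is weekly hours, $q$ is BMI (kg/m²), $x$ collects time-varying
covariates (degree, family size, high-skill occupation, England residence,
age), $\omega_i$ is an individual fixed effect and $\gamma$ is the
threshold. The kink term $(q-\gamma)_+$ makes the regression function
continuous at $\gamma$: the BMI slope is $\alpha$ below the threshold and
$\alpha + \delta$ above it, with no jump. A threshold near the clinical
obesity cutoff of 30 with $\delta < 0$ means hours rise with BMI in the
healthy range and fall beyond obesity.

BMI is endogenous: unobserved persistent traits affect both body weight
and labor supply. First-differencing removes $\omega_i$,

$$
\Delta y_{i} = \Delta x_i'\beta + \alpha\,\Delta q_i
  + \delta\left[(q_{i2}-\gamma)_+ - (q_{i1}-\gamma)_+\right]
  + \Delta\varepsilon_i,
$$

and four time-invariant childhood instruments — birth weight and the BMI
of the respondent, mother and father measured when the respondent was ten —
identify the remaining endogenous variation. At a fixed $\gamma$ the model
is linear, so estimation profiles a GMM criterion over a grid of candidate
thresholds.

## Estimation procedure

The moment vector stacks the instrument set
$z_i = (1, \Delta x_i', \text{childhood variables}')'$ against the
differenced residual. `fit_panel_threshold()`:

1. **Step 1** profiles $\gamma$ over the trimmed grid using the 2SLS weight
   $W_1 = (Z'Z/n)^{-1}$; at each grid value the linear coefficients have
   the standard closed form.
2. **Step 2** (default) rebuilds the weight from the centered sample
   covariance of the step-1 moment contributions and re-profiles $\gamma$
   once. The J-statistic is $n$ times the minimized criterion, with
   degrees of freedom equal to moments minus parameters, the threshold
   included (one, under the default design).
3. Ties at the grid minimum resolve toward the smaller threshold, for
   determinism.

**Grid and trimming.** Candidates lie between the $\tau/2$ and $1-\tau/2$
quantiles of the pooled BMI values, where the trim rate $\tau$ is the
*total* trimmed fraction (the headline specification trims 15 percent per
side, i.e. $\tau = 0.3$; the sensitivity panels use 0.2/0.3/0.4 in the
same convention). The default grid is 400 evenly spaced points;
`grid_type = "sample"` instead uses the observed BMI values inside the
support, and an explicit `gamma_grid` overrides both. Candidates leaving
less than `min_regime_fraction` (default 5%) of pooled observations in
either regime are skipped: they would make the differenced kink column
nearly collinear with the BMI-change column.

**Design columns.** In a single-cohort two-period panel the age difference
is constant (everyone ages by the same amount), so the differenced design
drops it and includes an intercept absorbing the common time trend; any
other zero-variance differenced covariate (for example a time-constant
residence indicator) is dropped the same way, with a message. The pooled
OLS benchmark keeps age.

**Standard errors.** The default is an analytic sandwich whose Jacobian
includes the threshold column
($\partial r_i/\partial\gamma = \delta\,[1\{q_{i2}\ge\gamma\} -
1\{q_{i1}\ge\gamma\}]$ — the kink moment is continuous and almost
everywhere differentiable in $\gamma$). A pairs bootstrap over individuals
(`se_method = "pairs_bootstrap"`) is offered as a robustness option because
the source analysis does not state how its threshold standard error was
computed; neither method is claimed to be that one. When $\hat\delta$ is
essentially zero the threshold direction is unidentified and its standard
error is reported as `NA` rather than a misleading number.

**Numerical safeguards.** Weight-matrix inversions fall back to a
ridge-regularized inverse with a warning when near-singular (e.g. in the
exact-fit limit where the moment covariance vanishes); rank-deficient
instrument cross-products raise an error naming the offending columns; a
just-identified Sargan test is an explicit error, never a silent zero.

## Benchmarks and diagnostics

Pooled OLS and the within (fixed-effects) estimator fit the restricted
$\delta = 0$ model; with two periods the within slopes equal
first-difference least squares exactly, which the tests assert as an
algebraic identity. Pooled standard errors are conventional homoskedastic
ones by default (a cluster-by-individual option exists, off by default to
mirror the usual pooled presentation). Instrument quality is reported as
the pooled first-stage R² of BMI levels on the four childhood variables,
the Cragg–Donald F of the differenced first stage against the bundled
Stock–Yogo critical values, and the classical (homoskedastic) Sargan
statistic on the linear first-differenced 2SLS residuals; the
heteroskedasticity-robust two-step J is reported separately by the
threshold fit.

## The synthetic cohort

The generator (`simulate_panel()`, defaults via `default_bcs_config()`)
emulates a two-wave cohort observed at ages 34 and 42: 828 women / 775 men
(the analysis sample sizes), instrument means and SDs, BMI means, SDs and
the 0.97 kg/m² mean drift, covariate proportions, and period-1 hours
means all match the cohort's published summary statistics for each arm.
The truth slopes default to the published panel-threshold estimates
(women: $\alpha = 4.656$, $\delta = -7.088$, $\gamma = 30.021$; men:
$-3.021$, $3.439$, $25.658$), and the intercept is computed in closed form
(`expected_kink_normal()`) so simulated hours center on the published
mean.

BMI is built as instrument index + individual effect + idiosyncratic
shock,

$$
q_{it} = \mu_1 + d\,1\{t=2\} + c_t's_i + \lambda\,\omega_i + u_{it},
$$

with the index loadings $c_t$ scaled so the instruments account for a
configurable share (default 0.20) of each period's BMI variance.
Endogeneity enters through $\lambda$: $\mathrm{cov}(q_{it},
\omega_i + \varepsilon_{it}) = \lambda\sigma_\omega^2$, calibrated to a
BMI–effect correlation of about 0.3. An optional `rho_u_eps` correlates
the transitory BMI and hours shocks — endogeneity that does *not*
difference out — and an optional measurement-noise knob perturbs recorded
(not structural) BMI.

Two generator features are structural requirements, not taste:

* **Period-specific index loadings** (`pi_stability`, default 0.625, the
  correlation of the instrument index across periods). Time-invariant
  instruments with fixed loadings difference out of the BMI-change
  equation entirely, leaving the below-threshold slope unidentified in the
  differenced moment system. Loadings that evolve between ages 34 and 42 —
  childhood anthropometrics predicting adult BMI differently at different
  ages — give the instruments genuine power for BMI *changes*; the default
  puts the differenced first-stage Cragg–Donald F in the low twenties at
  the cohort sample size, consistent with the strong instruments the
  source analysis reports.
* **Right-skewed childhood BMI instruments** (`instrument_skew`, default
  skewness 1 for the three BMI variables via a shifted lognormal matched
  exactly to the target mean and SD; birth weight stays normal). With
  jointly Gaussian instruments, every instrument moment of a function of
  the two BMI indices collapses onto a two-dimensional subspace, and the
  two endogenous regressor columns absorb exactly those directions: the
  threshold is then unidentified in population. Skewness — a well-known
  feature of real BMI distributions — is what lets the moments trace the
  kink.

**Noise scales.** The published slope estimates together with the BMI
dispersion imply an hours variance far larger than the published marginal
hours SD, so the two cannot be matched simultaneously; the generator
matches the means and BMI/instrument moments and sets the error components
($\sigma_\omega = 8$, $\sigma_\varepsilon = 6$ hours for women; 5.5/5.6
for men) so the residual scale is consistent with the published pooled R²
of roughly 0.27 (0.01 for men). One consequence is a heavy-tailed hours
margin: applying the observational 10–70 hours filter to synthetic data
truncates the outcome and distorts estimates, so the recovery experiments
in the test suite fit on unfiltered simulated samples, while the pipeline
(which mirrors the study's filter-first flow) documents the exclusions in
its audit.

**What a green test does not establish.** The generator draws instruments
independently of each other (a joint covariance hook exists), makes
education and skill monotone Bernoulli upgrades, family size a rounded
normal, and residence a rare-switch process; it does not model attrition,
survey weights, self-report measurement error (unless enabled), or the
joint covariate distribution. Green tests certify the estimator and
pipeline on a world with the stated first and second moments and kink
structure, not fidelity to the restricted cohort microdata.

## Known limitations

The threshold is weakly identified by the differenced moment system at
cohort sample sizes: only a low-dimensional projection of the kink misfit
is visible to nine moments, so the profile criterion is shallow in
$\gamma$. In the package's Monte-Carlo experiments the slope-change
$\delta$ is recovered essentially without bias, while $\hat\gamma$ has a
sampling SD of about 3 kg/m² — the same order as the published threshold
standard errors (2.9 for women) — and its occasional distant minima
contaminate $\hat\alpha$; sandwich intervals are conservative in that
regime. A full-information least-squares profile recovers the threshold
far more precisely on the same data, but it is only valid when no
endogeneity survives differencing, which is exactly what cannot be assumed
here. Practitioners should read the threshold point estimate together
with its profile (`objective_profile` in the fit) rather than in
isolation, and treat the trim-rate sensitivity panel as part of the
result.

Other scope limits: two periods only (no dynamic or $T > 2$ designs), no
discontinuous-jump threshold variant (the model is continuous by
construction), no weak-instrument-robust confidence sets, and no reader
for the restricted cohort's native file formats.

## Conventions resolved where the source is silent

* Trim rate is the total trimmed fraction, half per tail, so 0.2/0.3/0.4
  reproduce the sensitivity layout.
* The per-individual hours filter drops both records of an individual with
  one out-of-range period, keeping the panel balanced; pregnancy is
  filtered before the hours rule.
* Skill-subgroup membership uses the period-1 (age 34) label by default,
  with `period_rule` switches for period-2 or either-period definitions.
* Significance stars follow the printed thresholds ($p<0.001$, $<0.05$,
  $<0.1$) applied to normal-approximation z-tests.
* The Stock–Yogo constants ship as a plain-text table covering one and two
  endogenous regressors at the standard bias and size levels; the value
  16.85 corresponds to one endogenous regressor with four instruments at
  the 5 percent maximal-relative-bias criterion.
* Within-person correlation of the transitory hours shock across periods
  defaults to zero; the first-difference estimator is valid either way.
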