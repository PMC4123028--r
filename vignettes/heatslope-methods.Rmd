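---
title: "Modelling spatial variation in heat-related hospital admissions"
author: "heatslope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial variation in heat-related hospital admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`heatslope` estimates the short-term association between daily maximum
temperature and emergency hospital admissions during the warm season,
and how that association varies across the small areas of a city.  Its
inputs are four tidy tables: a daily admissions panel (`date`,
`area_id`, `count`), a daily weather series (`date`, `tmax`), an area
attribute table (population, planar centroid, candidate modifier
covariates), and a holiday calendar.  Counts are modelled directly —
no rates are precomputed — with each area's population entering as a
log offset, so the models describe admission *rates* per person-day.

The exposure is `tmax1`, the previous day's maximum dry-bulb
temperature.  A single linear lag-1 term is deliberate: it is the
specification that this class of subtropical admissions analyses has
found most predictive, and distributed-lag or nonlinear alternatives
are out of scope.  Two station series can be merged with
`combine_stations()` (mean where both present, the single record where
one is missing).  Days whose lagged exposure is unavailable are
dropped from the likelihood rather than imputed; at realistic
missingness (well under 1 %) imputation would be immaterial.

## The three models

All three are Bayesian Poisson regressions restricted to October–March
("warm season"), fitted by MCMC in JAGS.  The shared temporal
adjustment `time_j` has three blocks:

* **Day of week** — six indicators, Monday reference.
* **Holidays** — four category indicators (`standard`, `christmas`,
  `jan2`, `other`), non-holiday reference.  The categories reflect a
  robust empirical pattern: most public holidays depress scheduled
  admissions by roughly 15 %, Christmas Day by roughly 25 %, while
  2 January shows a rebound above baseline.
* **Day of year** — a separate natural cubic spline per warm season in
  the within-season day index, interior knots at equally spaced
  quantiles: 5 knots for interior seasons, 4 for the first and last
  (which are typically truncated by the study window).  Because each
  season gets its own block, the spline also absorbs interannual level
  shifts; season indicator columns are included so those shifts are
  identified next to a single global intercept.  A season's block is
  continuous across the new-year boundary, since the within-season
  index runs unbroken from October to March.

Model 1 pools the city: `log(mu_j) = alpha + log(E) + time_j +
gamma*tmax1_j`.  Model 2 gives each area its own slope `gamma_k`
(exchangeable normal), a random intercept `pi_k` (normal — the
conventional choice for log-linear random intercepts), and a smooth
spatial trend built from 2-df natural splines in the east–west and
north–south centroid coordinates (centred columns, so the trend is
identified next to the intercepts).  Model 3 adds the cross-level
regression `gamma_k = gamma* + lambda*sla.var_k + u_k`.  The residual
`u_k` is retained by default: the printed deterministic form would
attribute all unexplained slope variation to the modifier and
understate the uncertainty of `lambda`; `residual = FALSE` gives the
literal form.  Modifier covariates are centred and scaled internally
and `lambda` is rescaled to raw covariate units on output, so reported
effects do not depend on the internal standardisation.

## Priors, parameterisation, and the sampler

Location parameters get N(0, 1000) priors — read as variance 1000
(SD ≈ 31.6), the noninformative reading.  Variance components get
Gamma(1, 1) priors on the *precision*, the convention of JAGS-family
samplers; a literal on-variance option (`variance_prior = "variance"`)
is provided because the textual convention is genuinely ambiguous.

Two parameterisation choices matter for sampling quality:

* **Exposure scaling.**  Temperature is centred at its warm-season
  mean and divided by 10 inside the sampler, so slope-like parameters
  are sampled per 10 °C — the same unit in which they are reported —
  and rescaled to per-°C on output.  Besides conditioning, this keeps
  the Gamma(1, 1) precision prior weakly informative: on a per-°C
  scale the same prior would concentrate `sigma_gamma` near 0.3 °C⁻¹
  and swamp realistic between-area variation (~0.02 °C⁻¹).
* **Zero-mean random effects.**  The hierarchy is written as
  `gamma_k = gamma* + u_k` with `u_k ~ N(0, sigma^2)` and `gamma*`
  (and `lambda`) as fixed-effect coefficients of `tmax1` and
  modifier-by-`tmax1` interactions.  This is the same joint density as
  the centred form, but it lets the JAGS `glm` module block-update all
  regression coefficients (`glm::Generic`, `glm::REGamma2`), which
  mixes dramatically better than one-at-a-time slice sampling on this
  posterior.

Chain lengths default to the analysis tradition for these models:
5,000 burn-in + 5,000 retained draws per chain for model 1 and
2,000 + 2,000 for models 2–3, with 2 chains (enough for cross-chain
split-R-hat diagnostics at reasonable cost).  Fits warn when the
temperature slope's split R-hat exceeds 1.05.  All chains are
explicitly seeded, so identical settings reproduce bit-identical
draws.

## Reported quantities

Slopes are reported as percent change in admissions per 10 °C,
`100*(exp(10*gamma) − 1)`, summarised by the posterior median (robust
on the exponentiated scale; the mean is available by option) and the
central 95 % credible interval.  An area is classed significantly
positive/negative when its interval excludes zero; `slope_table()`
arranges areas the way published risk tables do (significant positives
descending, then significant negatives, then the rest) and reports the
significance counts.  `extra_admissions()` converts a percent effect
into the implied daily burden on the mean admission rate.

Modifier effects are reported per stated covariate unit (for example
density per 1,000 persons/km²) as the percent change in the
temperature slope, computed per draw as `100*lambda*unit/gamma*`; the
ratio form keeps the summary coherent draw-by-draw, and is stable
whenever the mean slope is clearly positive, as in all simulation
designs used here.

Spatial autocorrelation of the area slopes is tested with Moran's I.
The weights are unspecified in the underlying study design, so the
package defaults to row-standardised k-nearest-neighbour weights
(k = 5) on centroids — appropriate for the abstract synthetic
geometry, which has no polygons — and records the choice in the
result.  The p-value uses 999 random permutations, two-sided around
the permutation-null mean −1/(n−1), with `p = (r+1)/(n_perm+1)`; a
permutation test makes no normality assumption.  The statistic
requires at least three areas and non-constant values.

## The synthetic-data generator

The generator emulates the study conditions this pipeline targets:

* **Areas** (`gen_area_frame`): log-normal populations averaging
  ~6,050 (158 areas total ~956k residents); centroids uniform on the
  unit square; covariates drawn through a Gaussian copula so density,
  income and age structure are realistically inter-correlated, with
  marginals calibrated so that medians sit near 1,670 persons/km²
  (density, gamma), 5.95 % (high earners, beta), and plausible values
  for the over-65 and low-income shares.  Only medians are calibrated;
  the distributional shapes are conventional choices.
* **Weather** (`gen_weather`): sinusoid with annual mean 20.8 °C
  peaking in late January (January–February means above 25 °C, July
  near 15 °C) plus AR(1) noise (lag-1 correlation 0.7, innovation SD
  2.2 °C), clamped to a physically plausible band.
* **Holidays** (`gen_holiday_calendar`): Christmas Day, 2 January and
  a configurable list of ~8 further dates per year.
* **Admissions** (`simulate_admissions`): the exact generative
  direction of model 2/3 — per-area slopes
  `gamma_k = gamma* + lambda*(x_k − mean(x)) + N(0, sigma_gamma^2)`,
  intercepts `pi_k ~ N(0, sigma_pi^2)`, a quadratic spatial trend in
  the centred centroid coordinates, and Poisson counts.  The drawn
  `gamma_k`/`pi_k` are attached to the panel so recovery can be
  checked.  The day-of-year truth signal is a low-order sinusoid
  (winter-peaking, amplitude 0.10 on the log scale, with a 2 %/year
  trend), deliberately *not* expressed in the fitting spline's basis,
  so seasonal-adjustment tests are not circular.

Default truth values are the study conditions: baseline 193
admissions/day over 956,130 residents, mean slope `log(1.072)/10` per
°C (+7.2 % per 10 °C), slope SD 0.2 per 10 °C (which spreads area
slopes over roughly −30 % to +50 %, with tails reaching the extremes
seen across ~158 areas), intercept SD 0.3, holiday multipliers
0.85/0.75/1.15, weekend multipliers 0.85/0.80, and a density modifier
calibrated so +1,000 persons/km² raises the slope by 55.4 % of its
mean.  The slope is anchored at a reference temperature of 24 °C
(near the warm-season mean of the synthetic weather), so "baseline"
means the rate at an average warm-season day.

What the generator does **not** emulate: real polygon geographies
(contiguity is k-nearest-neighbour on abstract centroids),
overdispersion beyond Poisson, pollution co-exposure, heat-wave
persistence effects, and multi-station spatially varying exposure.
Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the stated generative model, not robustness
to real-data violations of it.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar dates; time zones are irrelevant at
  daily resolution.
* A warm season shorter than `knots + 2` days cannot support its
  spline block and is an error, as are degenerate (constant) centroid
  coordinates, constant modifier covariates, collinear modifier sets,
  zero-variance exposure, and non-integer counts.
* `combine_stations` requires identical date grids; mismatches are an
  error, not a silent join.
* Ties in k-nearest-neighbour distances resolve by index order, fixed
  under a given layout.
* Credible intervals are central (2.5/97.5 percentiles) with the
  default quantile rule.

## Problem sizes used in the tests

The test-suite simulations are scaled to run on a single CPU in
minutes while retaining power for the properties they check: citywide
recovery uses one to five warm seasons at ~193 admissions/day;
area-level checks use 20 areas over one or two seasons; modifier
coverage uses 20 replicates of 20 areas x 2 seasons with shortened
chains (the `glm`-module block sampler's low autocorrelation is what
makes short chains usable).  Where a check needs per-area precision —
e.g. that homogeneous true slopes collapse to near-identical estimates
— the fixture raises area populations instead of chain lengths, which
is the statistically relevant lever.

## Known limitations

Poisson dispersion is assumed exact; the random intercept absorbs
between-area but not within-area extra-Poisson variation.  The
spatial smoother is a directional spline, not a CAR/ICAR field — by
design, matching the modelling tradition this package follows.  The
modifier ratio summary is undefined in the measure-zero event
`gamma* = 0` on a draw, and unstable if the mean slope's posterior
straddles zero.  Moran's I weights for real polygon data (queen
contiguity) are not built in; supply any weight matrix to
`morans_i()` directly.
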