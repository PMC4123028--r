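# heatslope

Hierarchical Bayesian models for spatial variation in heat-related
hospital admissions.

## The problem

Hot days put people in hospital, but not uniformly: within one city,
some neighbourhoods are far more sensitive to heat than others, and
knowing *which* ones lets health agencies target warnings, tree
planting, insulation programmes and emergency resources.  `heatslope`
implements the full analysis chain for quantifying that spatial
variation from routinely collected data: daily admission counts per
small area, daily maximum temperature from one or two weather
stations, a holiday calendar, and an area attribute table (population,
centroids, census covariates).

Because admissions registers of this kind are confidential, the
package also ships a calibrated synthetic-data generator that
reproduces the generative structure of such a panel — a subtropical
city of ~956,000 residents in 158 small areas with about 193 emergency
admissions per day — so the entire pipeline is verifiable end to end
by parameter recovery.

## The models

All models are Poisson time-series regressions on warm-season days
(October–March) with a log link, fitted by MCMC (JAGS via `rjags`).
The exposure is `tmax1`, the previous day's maximum dry-bulb
temperature; `time_j` collects six day-of-week indicators, four
holiday-category indicators and a piecewise per-season natural-spline
day-of-year term (5 interior knots per season, 4 for the first and
last) that absorbs seasonality and long-term trends.

**Model 1 — citywide slope.** For day *j*,

    O_j ~ Poisson(mu_j)
    log(mu_j) = alpha + log(E) + time_j + gamma * tmax1_j

with `E` the total population offset.  `gamma` is reported as the
percent change in admissions per 10 °C: `100 * (exp(10 * gamma) − 1)`.

**Model 2 — area slopes.** For day *j* and area *k*,

    O_jk ~ Poisson(mu_jk)
    log(mu_jk) = alpha + log(E_k) + time_j + gamma_k * tmax1_j
                 + pi_k + smooth.area_k

where `gamma_k` is a normal random slope per area, `pi_k` a random
intercept, and `smooth.area_k` a 2-df spline in each of the east–west
and north–south centroid coordinates.  Areas whose 95 % credible
interval excludes zero are classed significantly positive or negative,
and Moran's I (permutation test on k-nearest-neighbour weights) checks
the slopes for residual spatial autocorrelation.

**Model 3 — cross-level modifiers.** As model 2, with

    gamma_k = gamma* + lambda * sla.var_k (+ u_k)

so `lambda` measures how an area covariate (population density, income
share, age structure, …) modifies heat sensitivity.

Priors are noninformative: N(0, 1000) on location parameters and
Gamma(1, 1) on precision components (a literal on-variance option is
available).  Defaults are 5,000 burn-in + 5,000 retained iterations
per chain for model 1 and 2,000 + 2,000 for models 2–3.

## Worked example

```r
library(heatslope)

# synthetic inputs: two warm seasons, the full 158-area city
weather  <- gen_weather(as.Date("2007-09-30"), as.Date("2009-03-31"), seed = 2)
calendar <- gen_holiday_calendar(2007:2009)
areas    <- gen_area_frame(158, seed = 4)
truth    <- simulation_truth()            # +7.2% per 10 C citywide
panel    <- simulate_admissions(areas, weather, calendar, truth, seed = 5)

cw <- citywide_counts(panel)
round(mean(cw$count), 1)
#> [1] 184.9                               # admissions per day, citywide

design   <- temporal_design(weather$date, calendar)
exposure <- lagged_exposure(weather)

fit <- fit_model1(panel, design, exposure,
                  population = sum(areas$population),
                  mcmc = mcmc_settings(2000, 2000, chains = 2, seed = 1))
fit
#> Hierarchical Poisson fit (model1): 4000 draws x 23 parameters, 2 chain(s)
#>   max split R-hat 1.001, min ESS 2433
#>   gamma: +8.2% per 10 C (95% CrI 5.4, 11.0)

pc <- percent_change(gamma_draws(fit))
extra_admissions(mean(cw$count), pc$estimate)
#> [1] 15.1                                # extra admissions/day per +10 C
```

The printed slope is the posterior median percent change in daily
admissions per 10 °C rise in the previous day's maximum temperature;
with two synthetic seasons at ~185 admissions/day it recovers the
simulated +7.2 % truth to within its credible interval, and the
implied burden is about 15 extra admissions on a day 10 °C hotter
than the one before.

The numbered scripts under `analysis/` run the full sequence at
study scale and write their tables under `results/`:
`01_simulate.R` (synthetic city), `02_design.R` (exposure and design
matrices), `03_fit_citywide.R` (model 1), `04_fit_area_slopes.R`
(model 2, slope table, Moran's I), `05_fit_modifiers.R` (model 3,
modifier table).

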