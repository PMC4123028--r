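Package: heatslope
Title: Hierarchical Bayesian Models for Spatial Variation in Heat-Related
    Hospital Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits hierarchical Bayesian Poisson time-series models relating
    daily hospital admissions to previous-day maximum temperature during the
    warm season, at citywide and small-area level.  Provides a calibrated
    synthetic-data generator for daily area-level admission panels, weather
    and holiday calendars so every stage can be verified by parameter
    recovery; temporal design construction (day-of-week and holiday
    indicators, piecewise per-season natural-spline seasonal adjustment,
    lagged exposure); three MCMC-fitted models (citywide slope, area-level
    random slopes with a directional spatial smoother, and cross-level
    modification of the slopes by area covariates); and summaries as percent
    change in admissions per 10 degrees Celsius with credible intervals,
    significance classes, modifier tables and a Moran's I spatial
    autocorrelation test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    splines,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
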