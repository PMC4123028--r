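#!/usr/bin/env Rscript

# Stage 5 — area-level modifiers of the heat slope (model 3).
#
# Regresses each area's temperature slope on area covariates:
# population density and the high-earner share singly, then both
# jointly (the multivariable form).  Effects are reported as percent
# change in the temperature-admissions slope per reporting unit
# (density per 1,000 persons/km^2, income per 1 percentage point).
# Uses the same reduced replica layout as stage 4 and expects its
# simulated inputs under results/area_run/.

suppressMessages(library(heatslope))

cfg <- default_config(
  seed = 2L, n_areas = 40L, years = 2008:2010,
  outdir = file.path("results", "area_run"),
  modifiers = list("density", "pct_high_income",
                   c("density", "pct_high_income")),
  mcmc = list(model1 = list(burn_in = 5000L, samples = 5000L, chains = 2L),
              area = list(burn_in = 600L, samples = 900L, chains = 1L)))
res <- run_pipeline(cfg, stages = c("design", "fit3", "summarize"))

tab <- modifier_table(res$fit3, cfg$unit_changes)
print(tab, digits = 3)
message("simulation truth: density raises the slope by 55.4% of its mean per 1,000/km^2;")
message("the income covariate has no direct effect on the slopes (its apparent")
message("effect arises through its correlation with density).")
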