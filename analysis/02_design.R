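#!/usr/bin/env Rscript

# Stage 2 — build the shared model design.
#
# Restricts the panel to the warm season (October-March), lags the
# exposure by one day (tmax1), and assembles the temporal design:
# 6 day-of-week indicators (reference Monday), 4 holiday indicators
# (reference none), and a separate natural-spline day-of-year block
# per warm season (5 interior knots, 4 for the first/last season),
# plus the 2-df east-west / north-south spatial spline basis over the
# area centroids.  Writes the design table to results/design.csv.

suppressMessages(library(heatslope))

cfg <- default_config(seed = 1L, outdir = "results")
res <- run_pipeline(cfg, stages = "design")

des <- res$design
message(sprintf("%d warm-season days across %d seasons; %d design columns",
                length(des$date), length(unique(des$season_id)),
                ncol(des$X)))
message(sprintf("exposure missing on %d day(s) (no predecessor)",
                sum(is.na(res$exposure$tmax1))))
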