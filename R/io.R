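#' Default pipeline configuration
#'
#' A single list drives the whole pipeline; it validates against a
#' small schema and round-trips to YAML.  Fields cover the simulation
#' size, the design choices (warm-season months, exposure lag, spline
#' knots), MCMC settings, the modifier list for the cross-level model,
#' and the spatial-weights specification.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_config(n_areas = 20, years = 2007:2008)
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "results",
    # simulation
    n_areas = 158L,
    years = 2007:2011,
    # inputs (used instead of simulation when all four are set)
    paths = list(panel = NULL, weather = NULL, areas = NULL,
                 calendar = NULL),
    missing_warn = 0.01,   # tolerated weather missingness fraction
    # design
    warm_months = c(10:12, 1:3),
    lag = 1L,
    interior_knots = 5L,
    edge_knots = 4L,
    spatial_df = 2L,
    # fitting
    mcmc = list(model1 = list(burn_in = 5000L, samples = 5000L,
                              chains = 2L),
                area = list(burn_in = 2000L, samples = 2000L,
                            chains = 2L)),
    modifiers = list("density", "pct_high_income",
                     c("density", "pct_high_income")),
    # summaries
    weights_k = 5L,
    n_perm = 999L,
    unit_changes = c(density = 1000, pct_high_income = 1,
                     pct_over65 = 1, pct_low_income = 1)
  )
  validate_config(modifyList(cfg, list(...)))
}

#' Validate a pipeline configuration
#'
#' @param cfg A configuration list (e.g. parsed from YAML).
#' @return The validated config, classed `run_config`.
#' @export
validate_config <- function(cfg) {
  need <- c("seed", "outdir", "n_areas", "years", "warm_months", "lag",
            "interior_knots", "edge_knots", "spatial_df", "mcmc",
            "modifiers", "weights_k", "n_perm", "unit_changes")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop_invalid("config error at field(s): %s (missing)",
                 paste(miss, collapse = ", "))
  chk <- function(ok, field, msg)
    if (!ok) stop_invalid("config error at field '%s': %s", field, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  chk(is.numeric(cfg$n_areas) && cfg$n_areas >= 2, "n_areas",
      "must be >= 2")
  chk(all(cfg$warm_months %in% 1:12), "warm_months",
      "must be months in 1..12")
  chk(cfg$lag >= 0, "lag", "must be >= 0")
  chk(cfg$interior_knots >= 1 && cfg$edge_knots >= 1,
      "interior_knots/edge_knots", "must be >= 1")
  chk(cfg$spatial_df >= 1, "spatial_df", "must be >= 1")
  for (m in c("model1", "area"))
    chk(all(c("burn_in", "samples", "chains") %in% names(cfg$mcmc[[m]])),
        paste0("mcmc$", m), "needs burn_in, samples, chains")
  structure(cfg, class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file of config fields; missing fields
#'   take their defaults.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  validate_config(modifyList(unclass(default_config()), y))
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

# ---- readers / writers -------------------------------------------------

#' Write pipeline inputs as tidy CSVs
#'
#' ISO-8601 dates, UTF-8, header row.  `write_truth` stores the
#' simulation ground truth (including drawn per-area effects) as YAML.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @name heat_io
#' @export
write_table_csv <- function(x, path) {
  df <- as.data.frame(x)
  if ("date" %in% names(df)) df$date <- format(as.Date(df$date), "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heat_io
#' @param truth A `simulation_truth`; `panel_truth` the `truth`
#'   attribute of a simulated panel.
#' @param panel_truth Optional drawn ground-truth list to include.
#' @export
write_truth <- function(truth, path, panel_truth = NULL) {
  y <- lapply(unclass(truth), function(v)
    if (is.numeric(v)) unclass(v) else v)
  if (!is.null(panel_truth))
    y$drawn <- lapply(panel_truth, function(v)
      if (is.numeric(v)) as.list(v) else v)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read and validate the four pipeline inputs
#'
#' Reads the admissions panel, weather series, area frame and holiday
#' calendar named in `config$paths`, with validation: dates must
#' parse, counts must be non-negative integers, (date, area) pairs must
#' be unique, any weather missingness raises a logged warning, and
#' missingness above `config$missing_warn` (default 1 percent) is
#' rejected.
#'
#' Wide day-by-area count matrices (a `date` column plus one column
#' per area) are accepted and normalised to the long format.
#'
#' @param config A `run_config` with `paths$panel`, `paths$weather`,
#'   `paths$areas`, `paths$calendar` set.
#' @return A list with `panel`, `weather`, `areas`, `calendar`.
#' @export
read_inputs <- function(config) {
  p <- config$paths
  for (f in c("panel", "weather", "areas", "calendar"))
    if (is.null(p[[f]]) || !file.exists(p[[f]]))
      stop_invalid("dependency error: missing input file for '%s'", f)
  panel <- read.csv(p$panel, stringsAsFactors = FALSE)
  if (!"count" %in% names(panel) && "date" %in% names(panel)) {
    # wide day x area matrix: melt to long
    areas_cols <- setdiff(names(panel), "date")
    panel <- data.frame(
      date = rep(panel$date, length(areas_cols)),
      area_id = rep(areas_cols, each = nrow(panel)),
      count = unlist(panel[areas_cols], use.names = FALSE))
  }
  panel$date <- as_date_strict(panel$date, "panel date")
  bad <- which(is.na(panel$count) | panel$count < 0 |
                 panel$count != round(panel$count))
  if (length(bad))
    stop_invalid("validation error: invalid counts at panel row(s) %s",
                 paste(head(bad, 5L), collapse = ", "))
  dup <- duplicated(panel[c("date", "area_id")])
  if (any(dup))
    stop_invalid("validation error: duplicate (date, area) at row(s) %s",
                 paste(head(which(dup), 5L), collapse = ", "))
  weather <- read.csv(p$weather, stringsAsFactors = FALSE)
  weather$date <- as_date_strict(weather$date, "weather date")
  fmiss <- mean(is.na(weather$tmax))
  if (fmiss > (config$missing_warn %||% 0.01))
    stop_invalid("validation error: weather missingness %.1f%% exceeds the %.1f%% threshold",
                 100 * fmiss, 100 * (config$missing_warn %||% 0.01))
  if (fmiss > 0)
    warning(sprintf("weather series has %.2f%% missing days", 100 * fmiss),
            call. = FALSE)
  areas <- read.csv(p$areas, stringsAsFactors = FALSE)
  if (any(areas$population <= 0))
    stop_invalid("validation error: non-positive population")
  if (anyDuplicated(areas$area_id))
    stop_invalid("validation error: duplicate area_id")
  calendar <- read.csv(p$calendar, stringsAsFactors = FALSE)
  calendar$date <- as_date_strict(calendar$date, "calendar date")
  class(panel) <- c("admissions_panel", "data.frame")
  class(weather) <- c("weather_series", "data.frame")
  class(areas) <- c("area_frame", "data.frame")
  class(calendar) <- c("holiday_calendar", "data.frame")
  list(panel = panel, weather = weather, areas = areas,
       calendar = calendar)
}

#' Serialise posterior draws to a long CSV
#'
#' Standard long draws format: `chain`, `draw`, `parameter`, `value`.
#'
#' @param fit A `heat_fit`.
#' @param path Output CSV path.
#' @export
write_fit_draws <- function(fit, path) {
  within_chain <- stats::ave(seq_along(fit$chain), fit$chain,
                             FUN = seq_along)
  long <- data.frame(
    chain = rep(fit$chain, ncol(fit$draws)),
    draw = rep(within_chain, ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Convergence report of a fit
#' @param fit A `heat_fit`.
#' @return A list with per-parameter split R-hat and effective sample
#'   size, and the worst values.
#' @export
convergence_report <- function(fit) {
  list(model = fit$model,
       max_rhat = max(fit$rhat, na.rm = TRUE),
       min_ess = min(fit$ess, na.rm = TRUE),
       rhat = as.list(round(fit$rhat, 4)),
       ess = as.list(round(fit$ess, 1)))
}

# ---- pipeline orchestration -------------------------------------------

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order — `simulate`, `design`,
#' `fit1`, `fit2`, `fit3`, `summarize` — passing artifacts in memory
#' and writing every output plus a JSON manifest (config hash, seed,
#' package versions, per-stage row counts and warnings) under
#' `config$outdir`.  With real input files named in `config$paths`,
#' `simulate` is replaced by [read_inputs()].  A stage whose upstream
#' artifact is unavailable fails with a dependency error naming it.
#' Re-running with an identical config and seed reproduces identical
#' outputs.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param stages Character subset of
#'   `c("simulate", "design", "fit1", "fit2", "fit3", "summarize")`.
#' @return Invisibly, a list of in-memory artifacts plus the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "design", "fit1",
                                    "fit2", "fit3", "summarize")) {
  config <- validate_config(config)
  allowed <- c("simulate", "design", "fit1", "fit2", "fit3", "summarize")
  if (length(setdiff(stages, allowed)))
    stop_invalid("unknown stage(s): %s",
                 paste(setdiff(stages, allowed), collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   versions = list(
                     package = as.character(utils::packageVersion("heatslope")),
                     R = paste(R.version$major, R.version$minor, sep = "."),
                     jags = as.character(rjags::jags.version())),
                   stages = list(), warnings = list())
  t_all <- Sys.time()
  log_stage <- function(name, rows) {
    message(sprintf("[%s] done (%d rows, %.1fs elapsed)", name, rows,
                    as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
    manifest$stages[[name]] <<- list(rows = rows)
  }
  need <- function(what) {
    if (is.null(art[[what]]))
      stop_invalid("dependency error: stage needs missing artifact '%s'",
                   what)
    art[[what]]
  }

  if ("simulate" %in% stages) {
    if (!is.null(config$paths$panel)) {
      art <- read_inputs(config)
    } else {
      art$areas <- gen_area_frame(config$n_areas, seed = config$seed)
      art$weather <- gen_weather(
        as.Date(sprintf("%d-01-01", min(config$years))),
        as.Date(sprintf("%d-12-31", max(config$years))),
        seed = config$seed + 1L)
      art$calendar <- gen_holiday_calendar(config$years)
      art$truth <- simulation_truth()
      art$panel <- simulate_admissions(art$areas, art$weather,
                                       art$calendar, art$truth,
                                       modifier_name = "density",
                                       seed = config$seed + 2L)
      write_truth(art$truth, file.path(config$outdir, "truth.yaml"),
                  panel_truth = attr(art$panel, "truth"))
    }
    write_table_csv(art$panel, file.path(config$outdir, "panel.csv"))
    write_table_csv(art$weather, file.path(config$outdir, "weather.csv"))
    write_table_csv(art$areas, file.path(config$outdir, "areas.csv"))
    write_table_csv(art$calendar, file.path(config$outdir, "calendar.csv"))
    log_stage("simulate", nrow(art$panel))
  }
  if ("design" %in% stages) {
    for (f in c("panel", "weather", "areas", "calendar"))
      if (is.null(art[[f]])) {
        fp <- file.path(config$outdir, paste0(f, ".csv"))
        if (!file.exists(fp))
          stop_invalid("dependency error: stage 'design' needs missing artifact '%s'", fp)
        cfg2 <- config
        cfg2$paths <- list(panel = file.path(config$outdir, "panel.csv"),
                           weather = file.path(config$outdir, "weather.csv"),
                           areas = file.path(config$outdir, "areas.csv"),
                           calendar = file.path(config$outdir, "calendar.csv"))
        art <- modifyList(art, read_inputs(cfg2))
        break
      }
    art$exposure <- lagged_exposure(art$weather, lag = config$lag)
    art$design <- temporal_design(art$weather$date, art$calendar,
                                  interior_knots = config$interior_knots,
                                  edge_knots = config$edge_knots,
                                  months = config$warm_months)
    art$basis <- spatial_basis(art$areas,
                               df_per_direction = config$spatial_df)
    write_table_csv(cbind(data.frame(date = art$design$date,
                                     season = art$design$season_id),
                          as.data.frame(art$design$X)),
                    file.path(config$outdir, "design.csv"))
    log_stage("design", length(art$design$date))
  }
  mk_mcmc <- function(which, offset = 0L) {
    s <- config$mcmc[[which]]
    mcmc_settings(s$burn_in, s$samples, chains = s$chains,
                  seed = config$seed + offset)
  }
  if ("fit1" %in% stages) {
    fit <- fit_model1(need("panel"), need("design"), need("exposure"),
                      population = sum(need("areas")$population),
                      mcmc = mk_mcmc("model1", 10L))
    art$fit1 <- fit
    write_fit_draws(fit, file.path(config$outdir, "fit1_draws.csv"))
    jsonlite::write_json(convergence_report(fit),
                         file.path(config$outdir, "fit1_convergence.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("fit1", nrow(fit$draws))
  }
  if ("fit2" %in% stages) {
    fit <- fit_model2(need("panel"), need("design"), need("exposure"),
                      need("areas"), need("basis"),
                      mcmc = mk_mcmc("area", 20L))
    art$fit2 <- fit
    write_fit_draws(fit, file.path(config$outdir, "fit2_draws.csv"))
    jsonlite::write_json(convergence_report(fit),
                         file.path(config$outdir, "fit2_convergence.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("fit2", nrow(fit$draws))
  }
  if ("fit3" %in% stages) {
    art$fit3 <- list()
    for (i in seq_along(config$modifiers)) {
      mods <- config$modifiers[[i]]
      nm <- paste(mods, collapse = "+")
      fit <- fit_model3(need("panel"), need("design"), need("exposure"),
                        need("areas"), need("basis"),
                        modifier_name = mods,
                        mcmc = mk_mcmc("area", 30L + i))
      art$fit3[[nm]] <- fit
      write_fit_draws(fit, file.path(config$outdir,
                                     sprintf("fit3_%s_draws.csv",
                                             gsub("[^A-Za-z0-9_]+", "_", nm))))
    }
    log_stage("fit3", length(art$fit3))
  }
  if ("summarize" %in% stages) {
    out <- list()
    if (!is.null(art$fit1)) {
      pc <- percent_change(gamma_draws(art$fit1))
      mean_rate <- mean(citywide_counts(need("panel"))$count)
      out$citywide <- list(pct_per_10C = pc$estimate,
                           cri = c(pc$lower, pc$upper),
                           extra_per_day = extra_admissions(mean_rate,
                                                            pc$estimate))
    }
    if (!is.null(art$fit2)) {
      tab <- slope_table(art$fit2, need("areas"))
      write_table_csv(tab, file.path(config$outdir, "slope_table.csv"))
      out$signif_counts <- as.list(attr(tab, "signif_counts"))
      W <- knn_weights(need("areas"), k = config$weights_k)
      mi <- morans_i(tab$pct_per_10C[match(need("areas")$area_id,
                                           tab$area_id)],
                     W, n_perm = config$n_perm, seed = config$seed)
      out$moran <- list(I = mi$I, p_value = mi$p_value,
                        weights = mi$weights_spec)
    }
    if (length(art$fit3)) {
      mt <- modifier_table(art$fit3, config$unit_changes)
      write_table_csv(mt, file.path(config$outdir, "modifier_table.csv"))
    }
    jsonlite::write_json(out, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("summarize", length(out))
  }
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(art, list(manifest = manifest)))
}
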