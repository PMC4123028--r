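#' MCMC settings for the Bayesian Poisson models
#'
#' Chain lengths follow the original analysis defaults: burn-in and
#' posterior sample of 5,000 iterations for the citywide model and
#' 2,000 for the area-level models, per chain.  Location parameters get
#' noninformative normal priors with variance 1000 (SD ~31.6); variance
#' components get Gamma(1,1) priors, by default on the precision scale
#' (the sampler's convention), with a literal on-variance option.
#'
#' @param burn_in Burn-in iterations per chain.
#' @param samples Retained iterations per chain.
#' @param chains Number of chains (2 by default, enough for cross-chain
#'   convergence diagnostics at half the cost of four).
#' @param adapt Adaptation iterations for the sampler.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain c uses stream `seed*100 + c`.
#' @param prior_sd SD of the normal priors on location parameters
#'   (default `sqrt(1000)`).
#' @param var_shape,var_rate Gamma hyperparameters for the variance
#'   components.
#' @param variance_prior `"precision"` places Gamma(shape, rate) on
#'   1/sigma^2; `"variance"` places it on sigma^2 itself.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burn_in = 5000L, samples = 5000L, chains = 2L,
                          adapt = 500L, thin = 1L, seed = 1L,
                          prior_sd = sqrt(1000), var_shape = 1,
                          var_rate = 1,
                          variance_prior = c("precision", "variance")) {
  variance_prior <- match.arg(variance_prior)
  vals <- c(burn_in, samples, chains, adapt, thin, prior_sd,
            var_shape, var_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all MCMC settings must be positive")
  structure(list(burn_in = as.integer(burn_in),
                 samples = as.integer(samples),
                 chains = as.integer(chains), adapt = as.integer(adapt),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_sd = prior_sd, var_shape = var_shape,
                 var_rate = var_rate, variance_prior = variance_prior),
            class = "mcmc_settings")
}

# ---- internal JAGS machinery ------------------------------------------

var_prior_block <- function(tau, sigma, mcmc) {
  if (mcmc$variance_prior == "precision") {
    sprintf("  %s ~ dgamma(var.shape, var.rate)\n  %s <- 1/sqrt(%s)\n",
            tau, sigma, tau)
  } else {
    s2 <- paste0("sig2.", sub("tau\\.", "", tau))
    sprintf("  %s ~ dgamma(var.shape, var.rate)\n  %s <- 1/%s\n  %s <- sqrt(%s)\n",
            s2, tau, s2, sigma, s2)
  }
}

run_jags <- function(model_string, data, monitor, mcmc) {
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed * 100L + c)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = TRUE)
  update(jm, mcmc$burn_in, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = mcmc$samples,
                      thin = mcmc$thin, progress.bar = "none")
}

# split-chain potential scale reduction factor per column
split_rhat <- function(draws, chain) {
  halves <- unlist(lapply(split(seq_len(nrow(draws)), chain), function(ix) {
    h <- length(ix) %/% 2L
    rep(c(1L, 2L), c(h, length(ix) - h)) + 2L * (chain[ix[1L]] - 1L)
  }), use.names = FALSE)
  apply(draws, 2L, function(v) {
    g <- split(v, halves)
    m <- lengths(g)[1L]
    W <- mean(vapply(g, var, 0))
    B <- m * var(vapply(g, mean, 0))
    if (W <= 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  })
}

make_heat_fit <- function(samp, model, rename, meta, mcmc, loglik_fun) {
  raw <- do.call(rbind, lapply(samp, as.matrix))
  chain <- rep(seq_along(samp), each = nrow(samp[[1L]]))
  draws <- raw[, names(rename), drop = FALSE]
  colnames(draws) <- unname(rename)
  # slope-like parameters are sampled per 10 C; report per degree C
  per10 <- attr(rename, "per10")
  if (length(per10))
    draws[, per10] <- draws[, per10, drop = FALSE] / 10
  rhat <- split_rhat(draws, chain)
  ess <- tryCatch(
    rowSums(vapply(samp, function(s)
      coda::effectiveSize(s[, names(rename), drop = FALSE]),
      numeric(length(rename)))),
    error = function(e) rep(NA_real_, length(rename)))
  names(ess) <- unname(rename)
  ll <- if (is.null(loglik_fun)) NULL else loglik_fun(draws)
  structure(list(model = model, draws = draws, chain = chain,
                 rhat = rhat, ess = ess, log_lik = ll,
                 meta = meta, mcmc = mcmc),
            class = "heat_fit")
}

#' @export
print.heat_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Poisson fit (%s): %d draws x %d parameters, %d chain(s)\n",
              x$model, nrow(x$draws), ncol(x$draws), max(x$chain)))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE)))
  g <- grep("^gamma", colnames(x$draws), value = TRUE)[1L]
  if (!is.na(g)) {
    pc <- percent_change(x$draws[, g])
    cat(sprintf("  %s: %+.1f%% per 10 C (95%% CrI %.1f, %.1f)\n",
                g, pc$estimate, pc$lower, pc$upper))
  }
  invisible(x)
}

#' Evaluate the Poisson log-linear predictor
#'
#' The log expected count for one observation:
#' `alpha + log(E) + x'beta + gamma*(tmax1 - t_center) + pi_k + smooth_k`.
#' Exposed so that the fitted rate can be reconstructed and checked
#' against the sampler independently.
#'
#' @param params Named list or vector with `alpha`, `beta` (vector
#'   aligned with `x`), and `gamma` (per degree C).
#' @param x Numeric vector of temporal design covariates.
#' @param tmax1 Lagged temperature exposure (degrees C); must be
#'   non-missing.
#' @param log_E Log population offset.
#' @param pi_k Area random intercept (default 0, citywide).
#' @param smooth_k Spatial smooth value for the area (default 0).
#' @param t_center Temperature centring constant used by the fit.
#' @return The log expected count (scalar).
#' @export
#' @examples
#' linear_predictor(list(alpha = log(2), beta = 0, gamma = 0),
#'                  x = 0, tmax1 = 30, log_E = log(100))  # log(200)
linear_predictor <- function(params, x, tmax1, log_E = 0, pi_k = 0,
                             smooth_k = 0, t_center = 0) {
  if (is.na(tmax1)) stop_invalid("missing exposure (tmax1)")
  beta <- params$beta %||% 0
  if (length(beta) != length(x) && !(length(beta) == 1L && all(beta == 0)))
    stop_invalid("beta and x lengths differ")
  params$alpha + log_E + sum(x * beta) +
    params$gamma * (tmax1 - t_center) + pi_k + smooth_k
}

# align panel counts, temporal design and exposure on complete rows
align_rows <- function(dates_panel, design, exposure) {
  ex <- exposure$tmax1[match(design$date, exposure$date)]
  keep <- design$date %in% dates_panel & !is.na(ex)
  if (!any(keep))
    stop_invalid("no usable rows: check that panel, design and exposure dates overlap")
  list(date = design$date[keep], X = design$X[keep, , drop = FALSE],
       t = ex[keep])
}

check_counts <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop_invalid("admission counts must be non-negative integers")
}

# ---- model 1: citywide slope ------------------------------------------

#' Fit the citywide temperature-admissions model
#'
#' A Bayesian Poisson regression of citywide daily admissions on the
#' previous day's maximum temperature during the warm season, adjusted
#' for day of week, holidays and the per-season seasonal spline:
#' `O_j ~ Poisson(mu_j)`,
#' `log(mu_j) = alpha + log(E) + time_j + gamma * tmax1_j`.
#' Temperature is centred at its warm-season mean and scaled to 10 C
#' units inside the sampler; the reported `gamma` is per degree C.
#'
#' @param panel Citywide daily counts: a `data.frame` with `date` and
#'   `count` (an `admissions_panel` is aggregated over areas first).
#' @param design A [temporal_design()].
#' @param exposure An [lagged_exposure()] series.
#' @param population Total population (the scalar offset `E`).
#' @param mcmc [mcmc_settings()]; defaults to 5,000 burn-in and 5,000
#'   retained iterations per chain.
#' @return A `heat_fit` with draws for `alpha`, the temporal
#'   coefficients and `gamma`; a warning is raised if the split R-hat
#'   for `gamma` exceeds 1.05.
#' @export
fit_model1 <- function(panel, design, exposure, population,
                       mcmc = mcmc_settings(5000L, 5000L)) {
  stopifnot(inherits(design, "temporal_design"))
  if ("area_id" %in% names(panel) && length(unique(panel$area_id)) > 1L)
    panel <- citywide_counts(panel)
  check_counts(panel$count)
  al <- align_rows(panel$date, design, exposure)
  O <- panel$count[match(al$date, panel$date)]
  if (sd(al$t) == 0)
    stop_invalid("degenerate design: exposure has zero variance")
  t_center <- mean(al$t)
  t10 <- (al$t - t_center) / 10
  ms <- paste0(
    "model {\n",
    "  for (j in 1:J) {\n",
    "    O[j] ~ dpois(mu[j])\n",
    "    log(mu[j]) <- logE + alpha + inprod(X[j,], beta[]) + g10 * t10[j]\n",
    "  }\n",
    "  alpha ~ dnorm(0, prec.loc)\n",
    "  g10 ~ dnorm(0, prec.loc)\n",
    "  for (p in 1:P) { beta[p] ~ dnorm(0, prec.loc) }\n",
    "}\n")
  data <- list(O = O, X = al$X, t10 = t10, J = length(O),
               P = ncol(al$X), logE = log(population),
               prec.loc = 1 / mcmc$prior_sd^2)
  samp <- run_jags(ms, data, c("alpha", "beta", "g10"), mcmc)
  rename <- c(alpha = "alpha",
              setNames(colnames(al$X), sprintf("beta[%d]", seq_len(ncol(al$X)))),
              g10 = "gamma")
  attr(rename, "per10") <- "gamma"
  meta <- list(t_center = t_center, population = population,
               dates = al$date, columns = colnames(al$X))
  loglik <- function(draws) {
    eta <- matrix(log(population), length(O), nrow(draws)) +
      rep(draws[, "alpha"], each = length(O)) +
      al$X %*% t(draws[, colnames(al$X), drop = FALSE]) +
      outer(al$t - t_center, draws[, "gamma"])
    colSums(dpois(O, exp(eta), log = TRUE))
  }
  fit <- make_heat_fit(samp, "model1", rename, meta, mcmc, loglik)
  if (fit$rhat[["gamma"]] > 1.05)
    warning("temperature slope may not have converged (split R-hat > 1.05)",
            call. = FALSE)
  fit
}

# shared assembly for the area-level models
area_model_data <- function(panel, design, exposure, areas, basis, mcmc) {
  stopifnot(inherits(design, "temporal_design"),
            inherits(basis, "spatial_basis"))
  check_counts(panel$count)
  if (!all(panel$area_id %in% areas$area_id))
    stop_invalid("panel contains areas missing from the area frame")
  if (!identical(sort(as.character(basis$area_id)),
                 sort(as.character(areas$area_id))))
    stop_invalid("spatial basis and area frame cover different areas")
  al <- align_rows(unique(panel$date), design, exposure)
  pd <- panel[panel$date %in% al$date, , drop = FALSE]
  day <- match(pd$date, al$date)
  area <- match(pd$area_id, areas$area_id)
  t_center <- mean(al$t)
  list(al = al, O = pd$count, day = day, area = area,
       t10 = (al$t - t_center) / 10, t_center = t_center,
       logE = log(areas$population),
       S = basis$S[match(areas$area_id, basis$area_id), , drop = FALSE],
       K = nrow(areas), area_id = as.character(areas$area_id))
}

# The area models are written with zero-mean random effects and the
# hierarchical means (gstar, lambda) as fixed-effect coefficients of
# t10 and modifier-by-t10 interactions.  This is the same joint density
# as the centred form g10[k] ~ N(gstar + lambda*x_k, sigma^2) but lets
# the JAGS glm module block-sample all coefficients (glm::Generic /
# glm::REGamma2), which mixes far better than one-at-a-time slicing.
area_model_string <- function(mcmc, modifier = FALSE, residual = TRUE) {
  mod_term <- if (modifier) " + inprod(XT[i,], lam10[])" else ""
  u_term <- if (residual) " + u[area[i]] * t10[day[i]]" else ""
  u_prior <- if (residual) "    u[k] ~ dnorm(0, tau.g)\n" else ""
  g_def <- if (modifier)
    "  for (k in 1:K) { g10[k] <- gstar10 + inprod(xm[k,], lam10[])%s }\n"
  else
    "  for (k in 1:K) { g10[k] <- gstar10%s }\n"
  g_def <- sprintf(g_def, if (residual) " + u[k]" else "")
  lam_prior <- if (modifier)
    "  for (m in 1:M) { lam10[m] ~ dnorm(0, prec.loc) }\n" else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    O[i] ~ dpois(mu[i])\n",
    "    log(mu[i]) <- alpha + logE[area[i]] + inprod(X[day[i],], beta[]) +\n",
    "      gstar10 * t10[day[i]]", mod_term, u_term, " +\n",
    "      pi[area[i]] + inprod(S[area[i],], delta[])\n",
    "  }\n",
    "  for (k in 1:K) {\n",
    u_prior,
    "    pi[k] ~ dnorm(0, tau.p)\n",
    "  }\n",
    g_def,
    "  alpha ~ dnorm(0, prec.loc)\n",
    "  gstar10 ~ dnorm(0, prec.loc)\n",
    lam_prior,
    "  for (p in 1:P) { beta[p] ~ dnorm(0, prec.loc) }\n",
    "  for (q in 1:Q) { delta[q] ~ dnorm(0, prec.loc) }\n",
    if (residual) var_prior_block("tau.g", "sigma.g10", mcmc) else "",
    var_prior_block("tau.p", "sigma.p", mcmc),
    "}\n")
}

area_loglik_fun <- function(md, beta_cols, delta_cols) {
  function(draws) {
    nd <- nrow(draws)
    etaT <- md$al$X %*% t(draws[, beta_cols, drop = FALSE])  # J x nd
    sm <- md$S %*% t(draws[, delta_cols, drop = FALSE])      # K x nd
    ll <- numeric(nd)
    gcols <- paste0("gamma_", md$area_id)
    pcols <- paste0("pi_", md$area_id)
    for (d in seq_len(nd)) {
      eta <- draws[d, "alpha"] + md$logE[md$area] + etaT[md$day, d] +
        draws[d, gcols][md$area] * (md$t10[md$day] * 10) +
        draws[d, pcols][md$area] + sm[md$area, d]
      ll[d] <- sum(dpois(md$O, exp(eta), log = TRUE))
    }
    ll
  }
}

#' Fit the area-level random-slope model
#'
#' Extends the citywide model to the areas of the city: each area k has
#' its own temperature slope `gamma_k`, modelled as an exchangeable
#' normal random effect around a common mean, a random intercept
#' `pi_k`, and a shared smooth spatial trend (east-west plus
#' north-south splines):
#' `log(mu_jk) = alpha + log(E_k) + time_j + gamma_k*tmax1_j + pi_k +
#' smooth.area_k`.
#'
#' @param panel An `admissions_panel` (long `date`/`area_id`/`count`).
#' @param design A [temporal_design()].
#' @param exposure A [lagged_exposure()] series.
#' @param areas An `area_frame` covering every panel area.
#' @param basis A [spatial_basis()] over the same areas.
#' @param mcmc [mcmc_settings()]; defaults to 2,000 burn-in and 2,000
#'   retained iterations per chain.
#' @return A `heat_fit` with draws for `alpha`, temporal coefficients,
#'   per-area `gamma_<area>` and `pi_<area>`, spatial coefficients
#'   `sp_*`, the mean slope `gamma_star` and the SDs `sigma_gamma`
#'   (per degree C) and `sigma_pi`.
#' @export
fit_model2 <- function(panel, design, exposure, areas, basis,
                       mcmc = mcmc_settings(2000L, 2000L)) {
  if (nrow(areas) < 2L) stop_invalid("the area-level model needs >= 2 areas")
  md <- area_model_data(panel, design, exposure, areas, basis, mcmc)
  ms <- area_model_string(mcmc, modifier = FALSE, residual = TRUE)
  data <- list(O = md$O, X = md$al$X, S = md$S, t10 = md$t10,
               day = md$day, area = md$area, logE = md$logE,
               P = ncol(md$al$X), K = md$K,
               Q = ncol(md$S), N = length(md$O),
               prec.loc = 1 / mcmc$prior_sd^2,
               var.shape = mcmc$var_shape, var.rate = mcmc$var_rate)
  samp <- run_jags(ms, data,
                   c("alpha", "beta", "g10", "pi", "delta", "gstar10",
                     "sigma.g10", "sigma.p"), mcmc)
  rename <- c(alpha = "alpha",
              setNames(colnames(md$al$X),
                       sprintf("beta[%d]", seq_len(ncol(md$al$X)))),
              setNames(paste0("gamma_", md$area_id),
                       sprintf("g10[%d]", seq_len(md$K))),
              setNames(paste0("pi_", md$area_id),
                       sprintf("pi[%d]", seq_len(md$K))),
              setNames(paste0("sp_", colnames(md$S)),
                       sprintf("delta[%d]", seq_len(ncol(md$S)))),
              gstar10 = "gamma_star",
              sigma.g10 = "sigma_gamma", sigma.p = "sigma_pi")
  attr(rename, "per10") <- c(paste0("gamma_", md$area_id), "gamma_star",
                             "sigma_gamma")
  meta <- list(t_center = md$t_center, area_id = md$area_id,
               dates = md$al$date, columns = colnames(md$al$X))
  fit <- make_heat_fit(samp, "model2", rename, meta, mcmc,
                       area_loglik_fun(md, colnames(md$al$X),
                                       paste0("sp_", colnames(md$S))))
  fit
}

#' Fit the cross-level modifier model
#'
#' Regresses the area temperature slopes on one or more area-level
#' covariates: `gamma_k = gamma_star + lambda * sla.var_k (+ u_k)`,
#' where `sla.var` is centred and scaled inside the sampler and
#' `lambda` is reported per raw covariate unit per degree C.  By
#' default a residual normal deviation `u_k` is retained so that
#' imperfect prediction of the slopes does not understate uncertainty;
#' `residual = FALSE` gives the literal deterministic form.
#'
#' @inheritParams fit_model2
#' @param modifier_name Character vector of one or more `areas` columns
#'   used as slope modifiers (a multivariable slope regression when
#'   more than one).
#' @param residual Keep the residual area deviation `u_k` (default
#'   TRUE).
#' @param mcmc [mcmc_settings()]; defaults as in [fit_model2()].
#' @return A `heat_fit` with, additionally, `lambda_<name>` draws (per
#'   raw covariate unit per degree C).
#' @export
fit_model3 <- function(panel, design, exposure, areas, basis,
                       modifier_name, residual = TRUE,
                       mcmc = mcmc_settings(2000L, 2000L)) {
  if (length(modifier_name) < 1L)
    stop_invalid("at least one modifier is required")
  missing_cols <- setdiff(modifier_name, names(areas))
  if (length(missing_cols))
    stop_invalid("modifier(s) not in area frame: %s",
                 paste(missing_cols, collapse = ", "))
  Xm_raw <- as.matrix(areas[, modifier_name, drop = FALSE])
  if (any(!is.finite(Xm_raw)))
    stop_invalid("modifier covariates must be finite")
  sds <- apply(Xm_raw, 2L, sd)
  if (any(sds == 0))
    stop_invalid("degenerate modifier: '%s' is constant across areas",
                 modifier_name[which(sds == 0)[1L]])
  Xm <- scale(Xm_raw)
  if (qr(Xm)$rank < ncol(Xm))
    stop_invalid("degenerate modifier set: covariates are collinear")
  md <- area_model_data(panel, design, exposure, areas, basis, mcmc)
  ms <- area_model_string(mcmc, modifier = TRUE, residual = residual)
  # cross-level interaction regressors: modifier value times exposure
  XT <- Xm[md$area, , drop = FALSE] * md$t10[md$day]
  data <- list(O = md$O, X = md$al$X, S = md$S, t10 = md$t10,
               day = md$day, area = md$area, logE = md$logE,
               xm = Xm[, , drop = FALSE], XT = XT, M = ncol(Xm),
               P = ncol(md$al$X), K = md$K,
               Q = ncol(md$S), N = length(md$O),
               prec.loc = 1 / mcmc$prior_sd^2,
               var.shape = mcmc$var_shape, var.rate = mcmc$var_rate)
  monitor <- c("alpha", "beta", "g10", "pi", "delta", "gstar10",
               "lam10", "sigma.p")
  if (residual) monitor <- c(monitor, "sigma.g10")
  samp <- run_jags(ms, data, monitor, mcmc)
  rename <- c(alpha = "alpha",
              setNames(colnames(md$al$X),
                       sprintf("beta[%d]", seq_len(ncol(md$al$X)))),
              setNames(paste0("gamma_", md$area_id),
                       sprintf("g10[%d]", seq_len(md$K))),
              setNames(paste0("pi_", md$area_id),
                       sprintf("pi[%d]", seq_len(md$K))),
              setNames(paste0("sp_", colnames(md$S)),
                       sprintf("delta[%d]", seq_len(ncol(md$S)))),
              gstar10 = "gamma_star",
              setNames(paste0("lambda_", modifier_name),
                       if (ncol(Xm) == 1L) "lam10" else
                         sprintf("lam10[%d]", seq_len(ncol(Xm)))),
              sigma.p = "sigma_pi")
  if (residual) rename <- c(rename, sigma.g10 = "sigma_gamma")
  attr(rename, "per10") <- c(paste0("gamma_", md$area_id), "gamma_star",
                             if (residual) "sigma_gamma")
  meta <- list(t_center = md$t_center, area_id = md$area_id,
               dates = md$al$date, columns = colnames(md$al$X),
               modifiers = modifier_name,
               modifier_center = attr(Xm, "scaled:center"),
               modifier_scale = attr(Xm, "scaled:scale"))
  fit <- make_heat_fit(samp, "model3", rename, meta, mcmc,
                       area_loglik_fun(md, colnames(md$al$X),
                                       paste0("sp_", colnames(md$S))))
  # lambda was sampled per 10 C per SD of the covariate; report per
  # degree C per raw covariate unit
  for (m in seq_along(modifier_name)) {
    cn <- paste0("lambda_", modifier_name[m])
    fit$draws[, cn] <- fit$draws[, cn] / (10 * sds[m])
  }
  fit
}

#' Extract per-area (or citywide) slope draws
#'
#' @param fit A `heat_fit`.
#' @param area Optional area id; omit to get the citywide slope
#'   (model 1) or the matrix of all per-area slopes (models 2-3).
#' @return A numeric vector of per-degree-C slope draws, or a matrix
#'   with one column per area.
#' @export
gamma_draws <- function(fit, area = NULL) {
  stopifnot(inherits(fit, "heat_fit"))
  if (fit$model == "model1") return(fit$draws[, "gamma"])
  if (is.null(area)) {
    cols <- paste0("gamma_", fit$meta$area_id)
    return(fit$draws[, cols, drop = FALSE])
  }
  cn <- paste0("gamma_", area)
  if (!cn %in% colnames(fit$draws))
    stop_invalid("no slope draws for area '%s'", area)
  fit$draws[, cn]
}
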