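# Fits in this file use deliberately short chains: the checks are
# parameter-recovery and equivalence properties with generous Monte
# Carlo allowances, not precision estimates.

test_that("linear predictor equals the hand-assembled dot product", {
  expect_equal(linear_predictor(list(alpha = 0, beta = 0, gamma = 0),
                                x = 0, tmax1 = 20), 0)
  expect_equal(linear_predictor(list(alpha = log(2), beta = 0, gamma = 0),
                                x = 0, tmax1 = 20, log_E = log(100)),
               log(200))
  set.seed(42)
  for (r in 1:5) {
    beta <- rnorm(3); x <- rnorm(3); a <- rnorm(1); g <- rnorm(1) / 50
    t1 <- runif(1, 15, 35); le <- rnorm(1); pk <- rnorm(1); sk <- rnorm(1)
    byhand <- a + le + x[1] * beta[1] + x[2] * beta[2] + x[3] * beta[3] +
      g * (t1 - 24) + pk + sk
    expect_equal(linear_predictor(list(alpha = a, beta = beta, gamma = g),
                                  x = x, tmax1 = t1, log_E = le,
                                  pi_k = pk, smooth_k = sk, t_center = 24),
                 byhand, tolerance = 1e-12)
  }
  expect_error(linear_predictor(list(alpha = 0, beta = 0, gamma = 0),
                                x = 0, tmax1 = NA), "exposure")
})

make_city_sim <- function(seed, gamma = log(1.072) / 10,
                          population = 956130) {
  w <- gen_weather(as.Date("2007-09-30"), as.Date("2008-03-31"),
                   seed = seed)
  cal <- gen_holiday_calendar(2007:2008)
  tr <- simulation_truth(gamma_star = gamma, sigma_gamma = 0, sigma_pi = 0,
                         spatial_coeffs = list(ew = c(0, 0), ns = c(0, 0)))
  p <- simulate_admissions(city_frame(population), w, cal, tr,
                           seed = seed + 100)
  list(panel = p, design = temporal_design(w$date, cal),
       exposure = lagged_exposure(w), truth = tr, weather = w,
       population = population)
}

test_that("citywide posterior agrees with the ML Poisson oracle and is reproducible", {
  sim <- make_city_sim(seed = 21)
  mc <- quick_mcmc(seed = 3, chains = 2, burn = 400, samples = 600)
  fit <- fit_model1(sim$panel, sim$design, sim$exposure,
                    population = 956130, mcmc = mc)
  # independent oracle: iteratively reweighted least squares via glm()
  al_t <- sim$exposure$tmax1[match(fit$meta$dates, sim$exposure$date)]
  X <- sim$design$X[sim$design$date %in% fit$meta$dates, , drop = FALSE]
  O <- sim$panel$count[match(fit$meta$dates, sim$panel$date)]
  ml <- glm(O ~ X + I((al_t - fit$meta$t_center) / 10),
            family = poisson(), offset = rep(log(956130), length(O)))
  ml_coef <- coef(ml)
  post <- fit$draws[, c("alpha", colnames(X), "gamma")]
  post_mean <- colMeans(post)
  post_sd <- apply(post, 2, sd)
  # undo the per-degree rescaling of gamma for the comparison
  post_mean["gamma"] <- post_mean["gamma"] * 10
  post_sd["gamma"] <- post_sd["gamma"] * 10
  # glm() drops aliased columns (e.g. a holiday category absent from
  # this window); compare the identified coefficients
  ok <- !is.na(ml_coef)
  expect_gt(sum(ok), 12)
  expect_true(all(abs(post_mean[ok] - ml_coef[ok]) <= 3 * post_sd[ok]))
  # seeded MCMC is bit-reproducible
  refit <- fit_model1(sim$panel, sim$design, sim$exposure,
                      population = 956130, mcmc = mc)
  expect_identical(fit$draws, refit$draws)
  # input validation
  bad <- sim$panel; bad$count[3] <- 1.5
  expect_error(fit_model1(bad, sim$design, sim$exposure, 956130, mc),
               "integer")
  flat_w <- sim$weather; flat_w$tmax <- 25
  expect_error(fit_model1(sim$panel, sim$design, lagged_exposure(flat_w),
                          956130, mc), "degenerate")
})

test_that("a null temperature effect is recovered as approximately zero", {
  # ten-fold population gives ~1,930 admissions/day, so the posterior
  # is tight enough for a +/-2 point check on a single replicate
  sim <- make_city_sim(seed = 31, gamma = 0, population = 9561300)
  fit <- fit_model1(sim$panel, sim$design, sim$exposure,
                    population = sim$population, mcmc = quick_mcmc(seed = 5))
  pc <- percent_change(gamma_draws(fit))
  expect_lt(abs(pc$estimate), 2)
})

test_that("credible intervals for the citywide slope cover the truth across replicates", {
  truth_pct <- 7.2
  covered <- 0L
  for (r in 1:20) {
    sim <- make_city_sim(seed = 200 + r)
    fit <- fit_model1(sim$panel, sim$design, sim$exposure,
                      population = 956130,
                      mcmc = quick_mcmc(seed = r, burn = 250,
                                        samples = 350, adapt = 150))
    pc <- percent_change(gamma_draws(fit))
    if (pc$lower <= truth_pct && truth_pct <= pc$upper)
      covered <- covered + 1L
  }
  # nominal 95% coverage; 17/20 allows binomial fluctuation
  expect_gte(covered, 17L)
})

test_that("the citywide slope is invariant to rescaling the offset", {
  sim <- make_city_sim(seed = 41)
  f1 <- fit_model1(sim$panel, sim$design, sim$exposure,
                   population = 956130, mcmc = quick_mcmc(seed = 6))
  f2 <- fit_model1(sim$panel, sim$design, sim$exposure,
                   population = 9561300, mcmc = quick_mcmc(seed = 6))
  # alpha absorbs the offset shift; gamma is unchanged up to MC error
  expect_equal(mean(f2$draws[, "alpha"]) - mean(f1$draws[, "alpha"]),
               -log(10), tolerance = 0.02)
  expect_equal(mean(f1$draws[, "gamma"]), mean(f2$draws[, "gamma"]),
               tolerance = 0.002)
})

test_that("area slopes are recovered in rank and coverage by the random-slope model", {
  w <- gen_weather(as.Date("2007-09-30"), as.Date("2009-03-31"), seed = 51)
  cal <- gen_holiday_calendar(2007:2009)
  ar <- gen_area_frame(20, seed = 52)
  tr <- simulation_truth(sigma_gamma = 0.02)
  p <- simulate_admissions(ar, w, cal, tr, seed = 53)
  des <- temporal_design(w$date, cal)
  ex <- lagged_exposure(w)
  fit <- fit_model2(p, des, ex, ar, spatial_basis(ar),
                    mcmc = quick_mcmc(seed = 7, burn = 250, samples = 400))
  truth_g <- attr(p, "truth")$gamma_k
  post_g <- colMeans(gamma_draws(fit))
  expect_gt(cor(post_g, truth_g[fit$meta$area_id], method = "spearman"),
            0.6)
  lo <- apply(gamma_draws(fit), 2, quantile, 0.025)
  hi <- apply(gamma_draws(fit), 2, quantile, 0.975)
  covered <- sum(lo <= truth_g[fit$meta$area_id] &
                   truth_g[fit$meta$area_id] <= hi)
  expect_gte(covered, 16L)  # ~95% of 20 areas, binomial tolerance
})

test_that("homogeneous truth yields near-identical area slope estimates", {
  # very populous areas make per-area slopes precise, so with
  # sigma_gamma = 0 the estimates must collapse onto a common value
  w <- gen_weather(as.Date("2007-09-30"), as.Date("2008-03-31"), seed = 61)
  cal <- gen_holiday_calendar(2007:2008)
  ar <- gen_area_frame(20, seed = 62, mean_population = 5e6)
  tr <- simulation_truth(sigma_gamma = 0, sigma_pi = 0.1)
  p <- simulate_admissions(ar, w, cal, tr, seed = 63)
  fit <- fit_model2(p, temporal_design(w$date, cal), lagged_exposure(w),
                    ar, spatial_basis(ar),
                    mcmc = quick_mcmc(seed = 8, burn = 250, samples = 400))
  pct <- 100 * (exp(10 * colMeans(gamma_draws(fit))) - 1)
  expect_lt(max(pct) - min(pct), 5)
})

test_that("relabelling areas permutes the slope posteriors with the labels", {
  w <- gen_weather(as.Date("2007-09-30"), as.Date("2008-03-31"), seed = 71)
  cal <- gen_holiday_calendar(2007:2008)
  ar <- gen_area_frame(3, seed = 72, mean_population = 5e5)
  tr <- simulation_truth(sigma_gamma = 0.03, sigma_pi = 0.2)
  p <- simulate_admissions(ar, w, cal, tr, seed = 73)
  des <- temporal_design(w$date, cal)
  ex <- lagged_exposure(w)
  mc <- quick_mcmc(seed = 9)
  fit_a <- fit_model2(p, des, ex, ar, spatial_basis(ar), mcmc = mc)
  perm <- c(3, 1, 2)
  ar_p <- ar[perm, ]
  fit_b <- fit_model2(p, des, ex, ar_p, spatial_basis(ar_p), mcmc = mc)
  ga <- colMeans(gamma_draws(fit_a))[paste0("gamma_", ar$area_id)]
  gb <- colMeans(gamma_draws(fit_b))[paste0("gamma_", ar$area_id)]
  expect_lt(max(abs(ga - gb)), 0.005)
})

test_that("modifier validation rejects degenerate requests", {
  fx <- fx_inputs(n_areas = 6, seed = 81)
  tr <- simulation_truth()
  p <- simulate_admissions(fx$areas, fx$weather, fx$calendar, tr, seed = 82)
  ar2 <- fx$areas
  ar2$density2 <- 2 * ar2$density
  expect_error(fit_model3(p, fx$design, fx$exposure, ar2, fx$basis,
                          c("density", "density2"), mcmc = quick_mcmc()),
               "collinear")
  ar3 <- fx$areas
  ar3$flat <- 1
  expect_error(fit_model3(p, fx$design, fx$exposure, ar3, fx$basis,
                          "flat", mcmc = quick_mcmc()), "constant")
  expect_error(fit_model3(p, fx$design, fx$exposure, fx$areas, fx$basis,
                          "not_there", mcmc = quick_mcmc()),
               "not in area frame")
})
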