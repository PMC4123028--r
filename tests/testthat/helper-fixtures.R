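# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# one warm season of inputs (Oct 2007 - Mar 2008) for n areas
fx_inputs <- function(n_areas = 10, seed = 4, years = 2007:2008,
                      start = "2007-09-30", end = "2008-03-31") {
  w <- gen_weather(as.Date(start), as.Date(end), seed = seed + 1)
  cal <- gen_holiday_calendar(years)
  ar <- gen_area_frame(n_areas, seed = seed)
  list(areas = ar, weather = w, calendar = cal,
       design = temporal_design(w$date, cal),
       exposure = lagged_exposure(w),
       basis = spatial_basis(ar))
}

# short MCMC settings for unit tests (mixing is good enough for the
# qualitative checks made here; acceptance tests use longer chains)
quick_mcmc <- function(seed = 1, chains = 1, burn = 300, samples = 400,
                       adapt = 200) {
  mcmc_settings(burn, samples, chains = chains, adapt = adapt, seed = seed)
}

# a one-area "citywide" frame for aggregate simulations
city_frame <- function(population = 956130) {
  structure(data.frame(area_id = "citywide", population = population,
                       centroid_ew = 0.5, centroid_ns = 0.5),
            class = c("area_frame", "data.frame"))
}

# simulation truth with every effect switched off except those given
flat_truth <- function(...) {
  defaults <- list(sigma_gamma = 0, sigma_pi = 0,
                   gamma_star = 0, lambda = 0,
                   holiday_effects = c(standard = 1, christmas = 1,
                                       jan2 = 1, other = 1),
                   dow_effects = c(Mon = 1, Tue = 1, Wed = 1, Thu = 1,
                                   Fri = 1, Sat = 1, Sun = 1),
                   seasonal_amplitude = 0, trend_per_year = 0,
                   spatial_coeffs = list(ew = c(0, 0), ns = c(0, 0)))
  do.call(simulation_truth, utils::modifyList(defaults, list(...)))
}

# ---- textbook natural cubic spline oracle -----------------------------
# Basis for the natural cubic spline space with the given interior and
# boundary knots, built from the truncated-power representation with
# the natural (linear-beyond-boundary) constraints: for knots
# xi_1 < ... < xi_K (interior plus the two boundaries),
#   N_1(x) = x,  N_{k+1}(x) = d_k(x) - d_{K-1}(x),
#   d_k(x)  = [(x - xi_k)^3_+ - (x - xi_K)^3_+] / (xi_K - xi_k).
# Together with the constant this spans the same space as splines::ns
# on the same knots (K - 1 basis functions here, ns gives K - 1 too).
ns_oracle <- function(x, interior, boundary) {
  xi <- sort(c(boundary, interior))
  K <- length(xi)
  pos3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pos3(x - xi[k]) - pos3(x - xi[K])) / (xi[K] - xi[k])
  cols <- c(list(x), lapply(seq_len(K - 2), function(k) d(k) - d(K - 1)))
  do.call(cbind, cols)
}

# check that two bases span the same function space on the same
# abscissae: every column of one is reproduced by regression on the
# other (plus intercept), and vice versa
expect_same_span <- function(A, B, tol = 1e-8) {
  res_onto <- function(Y, X) {
    f <- lm.fit(cbind(1, X), Y)
    max(abs(f$residuals))
  }
  expect_lt(res_onto(A, B), tol)
  expect_lt(res_onto(B, A), tol)
}

# ---- brute-force Moran's I oracle -------------------------------------
moran_brute <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
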