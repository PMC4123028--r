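test_that("area frame medians match the calibration city and generation is reproducible", {
  ar <- gen_area_frame(158, seed = 1)
  expect_equal(nrow(ar), 158)
  expect_true(all(ar$population > 0))
  expect_gt(median(ar$density), 1000)
  expect_lt(median(ar$density), 2500)
  expect_gt(median(ar$pct_high_income), 4)
  expect_lt(median(ar$pct_high_income), 8)
  expect_true(all(ar$centroid_ew >= 0 & ar$centroid_ew <= 1))
  # total population near the calibration city's ~956k
  expect_gt(sum(ar$population), 6e5)
  expect_lt(sum(ar$population), 1.4e6)

  tiny <- gen_area_frame(2, seed = 0)
  expect_equal(nrow(tiny), 2)
  expect_true(all(is.finite(as.matrix(tiny[, -1]))))
  expect_identical(gen_area_frame(25, seed = 9), gen_area_frame(25, seed = 9))
  expect_error(gen_area_frame(1, seed = 1), "n_areas")
})

test_that("synthetic weather reproduces the target climate", {
  w <- gen_weather(as.Date("2007-01-01"), as.Date("2011-12-31"), seed = 7)
  expect_equal(nrow(w), 1826)
  expect_gt(mean(w$tmax), 19.8)
  expect_lt(mean(w$tmax), 21.8)
  expect_true(all(w$tmax > 0 & w$tmax < 45))
  m <- as.integer(format(w$date, "%m"))
  expect_gt(mean(w$tmax[m == 1]), mean(w$tmax[m == 7]))
  expect_gt(mean(w$tmax[m %in% 1:2]), 24)   # summer peak above 25ish
  expect_lt(mean(w$tmax[m == 7]), 18)       # winter trough near 15
  one <- gen_weather(as.Date("2010-05-05"), as.Date("2010-05-05"), seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(is.finite(one$tmax))
  expect_identical(w, gen_weather(as.Date("2007-01-01"),
                                  as.Date("2011-12-31"), seed = 7))
  expect_error(gen_weather(as.Date("2008-01-01"), as.Date("2007-01-01"),
                           seed = 1), "precedes")
})

test_that("holiday calendar marks the named categories and nothing else", {
  cal <- gen_holiday_calendar(2007:2008)
  at <- function(d) cal$category[cal$date == as.Date(d)]
  expect_equal(at("2007-12-25"), "christmas")
  expect_equal(at("2008-01-02"), "jan2")
  expect_equal(at("2007-06-15"), "none")
  expect_equal(at("2007-01-26"), "standard")
  # each date appears exactly once
  expect_false(anyDuplicated(cal$date) > 0)
  expect_error(gen_holiday_calendar(integer(0)), "non-empty")
})

test_that("simulated citywide mean matches the closed-form Poisson rate", {
  # with all effects zero the daily citywide total is Poisson with mean
  # exp(alpha) * sum(E); calibrated to 193/day
  w <- gen_weather(as.Date("2007-01-01"), as.Date("2009-09-28"), seed = 2)
  cal <- gen_holiday_calendar(2007:2009)
  ar <- gen_area_frame(20, seed = 3)
  tr <- flat_truth(alpha = log(193 / sum(ar$population)))
  p <- simulate_admissions(ar, w, cal, tr, seed = 5)
  cw <- citywide_counts(p)
  expect_gte(nrow(cw), 1000)
  se <- sqrt(193 / nrow(cw))
  expect_lt(abs(mean(cw$count) - 193), 3 * se)
  # Poisson dispersion: variance ~ mean for the iid daily totals
  disp <- sum((cw$count - mean(cw$count))^2) / mean(cw$count)
  n <- nrow(cw)
  expect_gt(disp, qchisq(0.001, n - 1))
  expect_lt(disp, qchisq(0.999, n - 1))
})

test_that("degenerate slope variance gives identical area slopes", {
  fx <- fx_inputs(n_areas = 5, seed = 8)
  tr <- simulation_truth(sigma_gamma = 0)
  p <- simulate_admissions(fx$areas, fx$weather, fx$calendar, tr, seed = 1)
  g <- attr(p, "truth")$gamma_k
  expect_equal(unname(g), rep(tr$gamma_star, 5))
})

test_that("single-area slope is recovered by an independent Poisson GLM", {
  # oracle: ML Poisson regression of simulated counts on tmax1
  w <- gen_weather(as.Date("2000-01-01"), as.Date("2027-05-19"), seed = 6)
  tr <- flat_truth(alpha = log(150 / 956130),
                   gamma_star = log(1.072) / 10)
  cal <- gen_holiday_calendar(2000:2027)
  p <- simulate_admissions(city_frame(), w, cal, tr, seed = 9)
  expect_gte(nrow(p), 10000)
  t1 <- w$tmax[match(p$date - 1, w$date)]
  fit <- glm(p$count ~ I(t1 - tr$tmax_ref) + offset(rep(log(956130), nrow(p))),
             family = poisson())
  est <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(est - tr$gamma_star), 3 * se)
})

test_that("drawn area slopes regress back to the modifier effect", {
  w <- gen_weather(as.Date("2007-12-01"), as.Date("2007-12-31"), seed = 2)
  cal <- gen_holiday_calendar(2007)
  ar <- gen_area_frame(300, seed = 11)
  tr <- simulation_truth()
  p <- simulate_admissions(ar, w, cal, tr, modifier_name = "density",
                           seed = 3)
  g <- attr(p, "truth")$gamma_k
  x <- ar$density - mean(ar$density)
  fit <- lm(g ~ x)
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(coef(fit)[2] - tr$lambda), 3 * se)
  # and the mean slope is centred on gamma*
  expect_lt(abs(mean(g) - tr$gamma_star), 3 * tr$sigma_gamma / sqrt(300))
})

test_that("simulation is reproducible and validates its inputs", {
  fx <- fx_inputs(n_areas = 3, seed = 2)
  tr <- simulation_truth()
  p1 <- simulate_admissions(fx$areas, fx$weather, fx$calendar, tr, seed = 4)
  p2 <- simulate_admissions(fx$areas, fx$weather, fx$calendar, tr, seed = 4)
  expect_identical(p1, p2)
  # first weather date is excluded (no lagged exposure)
  expect_false(fx$weather$date[1] %in% p1$date)
  short_cal <- fx$calendar[fx$calendar$date < as.Date("2008-01-01"), ]
  expect_error(simulate_admissions(fx$areas, fx$weather, short_cal, tr,
                                   seed = 1), "calendar")
  expect_error(simulate_admissions(fx$areas, fx$weather, fx$calendar, tr,
                                   modifier_name = "nope", seed = 1),
               "modifier")
})
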