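#' Generate a synthetic area attribute table
#'
#' Produces the static per-area inputs of the analysis: a population
#' count used as the Poisson offset, a planar centroid on the unit
#' square, and four candidate modifier covariates (population density,
#' percent of high earners, percent aged over 65, percent on low
#' incomes).  Marginal distributions are calibrated so that at ~158
#' areas the medians resemble a city of just under a million residents:
#' median density near 1,670 persons/km^2 and median percent of high
#' earners near 5.95.
#'
#' Covariates are drawn through a Gaussian copula so they are mutually
#' correlated: density correlates positively with the low-income share
#' and negatively with the high-earner share, a typical inner-city
#' deprivation pattern.
#'
#' @param n_areas Number of areas (>= 2; the area-level models need at
#'   least two areas).
#' @param seed Integer RNG seed; the same seed reproduces the same table.
#' @param mean_population Mean area population.  Default 956130/158.
#' @param corr_strength Multiplier in `[0, 1]` on the default covariate
#'   correlation template; 0 gives independent covariates.
#'
#' @return A `data.frame` of class `area_frame` with columns `area_id`,
#'   `population`, `centroid_ew`, `centroid_ns`, `density`,
#'   `pct_high_income`, `pct_over65`, `pct_low_income`.
#' @export
#' @examples
#' ar <- gen_area_frame(158, seed = 1)
#' median(ar$density)
gen_area_frame <- function(n_areas, seed, mean_population = 956130 / 158,
                           corr_strength = 1) {
  if (n_areas < 2)
    stop_invalid("n_areas must be >= 2 (the area-level models need at least two areas)")
  if (corr_strength < 0 || corr_strength > 1)
    stop_invalid("corr_strength must be in [0, 1]")
  set.seed(as.integer(seed))
  sdlog <- 0.6
  population <- rlnorm(n_areas, meanlog = log(mean_population) - sdlog^2 / 2,
                       sdlog = sdlog)
  centroid_ew <- runif(n_areas)
  centroid_ns <- runif(n_areas)

  # correlation template: density / high income / over 65 / low income
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.25  # dense areas have fewer high earners
  R[1, 4] <- R[4, 1] <- 0.30   # ... and more low-income residents
  R[2, 4] <- R[4, 2] <- -0.40
  R[3, 4] <- R[4, 3] <- 0.20   # older areas somewhat poorer
  R <- diag(4) + corr_strength * (R - diag(4))
  L <- tryCatch(chol(R), error = function(e)
    stop_invalid("covariate correlation template is not positive definite"))
  Z <- matrix(rnorm(n_areas * 4), n_areas, 4) %*% L
  U <- pnorm(Z)

  areas <- data.frame(
    area_id = sprintf("area_%03d", seq_len(n_areas)),
    population = population,
    centroid_ew = centroid_ew,
    centroid_ns = centroid_ns,
    # gamma(shape 2, scale 1000): median ~1,678 persons/km^2
    density = stats::qgamma(U[, 1], shape = 2, scale = 1000),
    # beta tuned to a median high-earner share near 5.95 percent
    pct_high_income = 100 * qbeta(U[, 2], 2, 26.7),
    pct_over65 = 100 * qbeta(U[, 3], 5, 32),
    pct_low_income = 100 * qbeta(U[, 4], 4, 16),
    stringsAsFactors = FALSE
  )
  class(areas) <- c("area_frame", "data.frame")
  areas
}

#' Generate a synthetic daily maximum-temperature series
#'
#' Daily maximum dry-bulb temperature with a Brisbane-like climate: a
#' sinusoidal annual cycle peaking in late January (monthly means above
#' 25 C in January-February, near 15 C in July), an annual mean of
#' 20.8 C, and AR(1) day-to-day noise.  Values are clamped to a
#' physically plausible band.
#'
#' @param start_date,end_date Calendar dates bounding the series
#'   (inclusive); `end_date` must not precede `start_date`.
#' @param seed Integer RNG seed.
#' @param annual_mean Mean of the seasonal cycle (degrees C).
#' @param amplitude Half-range of the seasonal cycle (degrees C).
#' @param peak_doy Day of year at which the cycle peaks (default 25,
#'   late January).
#' @param ar Lag-1 autocorrelation of the noise.
#' @param innov_sd SD of the AR(1) innovations (degrees C).
#'
#' @return A `data.frame` of class `weather_series` with columns `date`
#'   and `tmax`.
#' @export
#' @examples
#' w <- gen_weather(as.Date("2007-01-01"), as.Date("2011-12-31"), seed = 7)
#' mean(w$tmax)
gen_weather <- function(start_date, end_date, seed, annual_mean = 20.8,
                        amplitude = 5.5, peak_doy = 25, ar = 0.7,
                        innov_sd = 2.2) {
  start_date <- as_date_strict(start_date, "start_date")
  end_date <- as_date_strict(end_date, "end_date")
  if (end_date < start_date)
    stop_invalid("end_date precedes start_date")
  set.seed(as.integer(seed))
  date <- seq(start_date, end_date, by = "day")
  n <- length(date)
  doy <- as.integer(format(date, "%j"))
  seasonal <- annual_mean +
    amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  eps <- numeric(n)
  eps[1L] <- rnorm(1L, 0, innov_sd / sqrt(1 - ar^2))
  innov <- rnorm(n, 0, innov_sd)
  for (i in seq_len(n)[-1L]) eps[i] <- ar * eps[i - 1L] + innov[i]
  tmax <- pmin(pmax(seasonal + eps, 0.5), 44.5)
  structure(data.frame(date = date, tmax = tmax),
            class = c("weather_series", "data.frame"))
}

#' Generate a holiday calendar
#'
#' Marks Christmas Day (category `christmas`), 2 January (`jan2`) and a
#' configurable set of about eight further public holidays per year
#' (`standard`); every other date is `none`.  The categories mirror the
#' empirical pattern that most holidays depress admissions by ~15
#' percent, Christmas Day by ~25 percent, while 2 January raises them.
#'
#' @param years Integer vector of calendar years (non-empty).
#' @param standard_dates Character vector of `"MM-DD"` strings marked as
#'   `standard` in every year (Christmas and 2 January take precedence).
#' @param other_dates `"MM-DD"` strings for the residual `other`
#'   category (empty by default).
#'
#' @return A `data.frame` of class `holiday_calendar` with one row per
#'   date of the requested years and columns `date`, `category`.
#' @export
#' @examples
#' cal <- gen_holiday_calendar(2007)
#' cal$category[cal$date == as.Date("2007-12-25")]
gen_holiday_calendar <- function(years,
                                 standard_dates = c("01-01", "01-26",
                                                    "04-25", "05-04",
                                                    "06-08", "08-12",
                                                    "10-05", "12-26"),
                                 other_dates = character()) {
  if (length(years) == 0)
    stop_invalid("years must be non-empty")
  years <- sort(unique(as.integer(years)))
  date <- seq(as.Date(sprintf("%d-01-01", min(years))),
              as.Date(sprintf("%d-12-31", max(years))), by = "day")
  date <- date[as.integer(format(date, "%Y")) %in% years]
  mmdd <- format(date, "%m-%d")
  category <- rep("none", length(date))
  category[mmdd %in% standard_dates] <- "standard"
  category[mmdd %in% other_dates] <- "other"
  category[mmdd == "12-25"] <- "christmas"
  category[mmdd == "01-02"] <- "jan2"
  structure(data.frame(date = date, category = category),
            class = c("holiday_calendar", "data.frame"))
}

#' Simulate a daily area-level admissions panel
#'
#' Draws admission counts from the same hierarchical Poisson process the
#' models estimate: for day j and area k,
#' \deqn{O_{jk} \sim Poisson(\mu_{jk}),\quad
#'   \log\mu_{jk} = \alpha + \log E_k + time_j +
#'   \gamma_k (tmax1_j - t_{ref}) + \pi_k + smooth.area_k,}
#' where `time_j` collects the holiday and day-of-week log multipliers
#' plus the smooth day-of-year signal, `tmax1_j` is the previous day's
#' maximum temperature, and the per-area slope is
#' \eqn{\gamma_k = \gamma^* + \lambda (x_k - \bar x) + u_k},
#' \eqn{u_k \sim N(0, \sigma_\gamma^2)} (with \eqn{\lambda = 0} when no
#' modifier is requested).  The first weather date receives no counts
#' because its lagged exposure is undefined.
#'
#' The drawn per-area slopes and intercepts are attached as ground truth
#' (`attr(panel, "truth")`) so recovery can be checked downstream.
#'
#' @param areas An `area_frame` (see [gen_area_frame()]).
#' @param weather A `weather_series` covering the panel dates plus the
#'   preceding day.
#' @param calendar A `holiday_calendar` covering all panel dates.
#' @param truth A [simulation_truth()] object.
#' @param modifier_name Optional name of an `areas` column whose centred
#'   value shifts each area's slope by `truth$lambda` per unit.
#' @param seed Integer RNG seed.
#'
#' @return A `data.frame` of class `admissions_panel` with columns
#'   `date`, `area_id`, `count`, plus a `truth` attribute holding the
#'   drawn `gamma_k`, `pi_k` and the fixed `smooth_area` values.
#' @export
simulate_admissions <- function(areas, weather, calendar, truth,
                                modifier_name = NULL, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!all(c("date", "tmax") %in% names(weather)))
    stop_invalid("weather must have columns date, tmax")
  if (nrow(weather) < 2)
    stop_invalid("weather must span at least two days (one is lost to the lag)")
  dates <- weather$date[-1L]
  if (!all(dates %in% calendar$date))
    stop_invalid("holiday calendar does not cover all panel dates")
  if (!is.null(modifier_name) && !modifier_name %in% names(areas))
    stop_invalid("modifier '%s' is not a column of the area frame",
                 modifier_name)
  set.seed(as.integer(seed))
  K <- nrow(areas)
  J <- length(dates)

  # per-area components
  xmod <- if (is.null(modifier_name)) rep(0, K) else {
    x <- areas[[modifier_name]]
    x - mean(x)
  }
  lam <- if (is.null(modifier_name)) 0 else truth$lambda
  gamma_k <- truth$gamma_star + lam * xmod +
    rnorm(K, 0, truth$sigma_gamma)
  pi_k <- rnorm(K, 0, truth$sigma_pi)
  ew <- areas$centroid_ew - mean(areas$centroid_ew)
  ns <- areas$centroid_ns - mean(areas$centroid_ns)
  smooth_area <- truth$spatial_coeffs$ew[1] * ew +
    truth$spatial_coeffs$ew[2] * ew^2 +
    truth$spatial_coeffs$ns[1] * ns +
    truth$spatial_coeffs$ns[2] * ns^2

  # per-day components
  tmax1 <- weather$tmax[-nrow(weather)]      # previous day's tmax
  cat_j <- calendar$category[match(dates, calendar$date)]
  hol_mult <- ifelse(cat_j == "none", 1,
                     truth$holiday_effects[cat_j])
  dow_idx <- (as.integer(format(dates, "%u")))  # 1 = Monday
  dow_mult <- truth$dow_effects[dow_idx]
  doy <- as.integer(format(dates, "%j"))
  yrs_elapsed <- as.numeric(dates - dates[1L]) / 365.25
  season_sig <- truth$seasonal_amplitude *
    cos(2 * pi * (doy - 196) / 365.25) +
    truth$trend_per_year * yrs_elapsed
  time_j <- log(hol_mult) + log(dow_mult) + season_sig

  eta <- matrix(truth$alpha, J, K) +
    matrix(log(areas$population), J, K, byrow = TRUE) +
    matrix(time_j, J, K) +
    outer(tmax1 - truth$tmax_ref, gamma_k) +
    matrix(pi_k + smooth_area, J, K, byrow = TRUE)
  count <- rpois(J * K, exp(as.vector(eta)))

  panel <- data.frame(
    date = rep(dates, K),
    area_id = rep(areas$area_id, each = J),
    count = count,
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$date, panel$area_id), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(gamma_k = setNames(gamma_k, areas$area_id),
                               pi_k = setNames(pi_k, areas$area_id),
                               smooth_area = setNames(smooth_area,
                                                      areas$area_id),
                               alpha = truth$alpha,
                               lambda = lam,
                               tmax_ref = truth$tmax_ref,
                               modifier = modifier_name)
  class(panel) <- c("admissions_panel", "data.frame")
  panel
}

#' Aggregate an admissions panel to a citywide daily series
#'
#' Sums counts over areas for each date, the input to the citywide model.
#'
#' @param panel An `admissions_panel`.
#' @return A `data.frame` with columns `date`, `count`.
#' @export
citywide_counts <- function(panel) {
  agg <- aggregate(count ~ date, data = as.data.frame(panel), FUN = sum)
  agg[order(agg$date), , drop = FALSE]
}
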