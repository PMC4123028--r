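#' Ground-truth parameter set for the admissions simulator
#'
#' Bundles every parameter of the generative model behind
#' [simulate_admissions()]: the citywide baseline rate, the temperature
#' slope and its between-area heterogeneity, the cross-level modifier
#' effect, area random intercepts, holiday and day-of-week multipliers,
#' the smooth day-of-year signal and the directional spatial trend.
#'
#' Defaults are calibrated to a subtropical city of ~956,000 residents
#' split over ~158 small areas with about 193 emergency admissions per
#' day: the mean temperature slope corresponds to a 7.2 percent rise in
#' admissions per 10 degrees C, most holidays lower admissions by about
#' 15 percent, Christmas Day by about 25 percent, while 2 January raises
#' them, and weekends run 15-20 percent below weekdays.
#'
#' @param alpha Baseline log admission rate per person-day at reference
#'   conditions (Monday, no holiday, zero seasonal signal, temperature at
#'   `tmax_ref`).  The default gives 193 admissions/day for a total
#'   population of 956,130.
#' @param gamma_star Citywide mean temperature slope, log scale per
#'   degree C.  Default `log(1.072)/10`: +7.2 percent per 10 degrees C.
#' @param sigma_gamma SD of area slope deviations around the mean slope
#'   (per degree C).  Default 0.02 (0.2 per 10 degrees C), which spreads
#'   area slopes over roughly -30 to +50 percent per 10 degrees C, with
#'   tails reaching the more extreme values seen across ~158 areas.
#' @param lambda Cross-level modifier effect: change in the slope (per
#'   degree C) per unit of the centred modifier covariate.  The default
#'   is calibrated for population density so that +1,000 persons/km^2
#'   raises the temperature slope by 55.4 percent of its mean.  Ignored
#'   unless a modifier is requested in [simulate_admissions()].
#' @param sigma_pi SD of area random intercepts (log scale).
#' @param holiday_effects Named multiplicative rate factors for holiday
#'   categories `standard`, `christmas`, `jan2`, `other`.
#' @param dow_effects Seven named multiplicative factors Mon..Sun; the
#'   Monday reference must equal 1.
#' @param seasonal_amplitude Log-scale amplitude of the smooth
#'   day-of-year signal (a sinusoid peaking in mid winter, so the truth
#'   signal is not expressed in the fitting spline's own basis).
#' @param trend_per_year Log-scale linear long-term trend per year.
#' @param spatial_coeffs List with numeric vectors `ew` and `ns`, the
#'   linear and quadratic coefficients of the smooth spatial trend in the
#'   centred east-west and north-south centroid coordinates.
#' @param tmax_ref Reference temperature (degrees C) at which `alpha` is
#'   anchored; the simulator uses `gamma_k * (tmax1 - tmax_ref)`.
#'   Default 24, near the warm-season mean of the synthetic weather.
#'
#' @return An object of class `simulation_truth` (a validated list).
#' @export
#' @examples
#' tr <- simulation_truth()
#' exp(tr$gamma_star * 10) - 1  # +7.2% per 10 C
simulation_truth <- function(alpha = log(193 / 956130),
                             gamma_star = log(1.072) / 10,
                             sigma_gamma = 0.02,
                             lambda = 0.554 * log(1.072) / 10 / 1000,
                             sigma_pi = 0.3,
                             holiday_effects = c(standard = 0.85,
                                                 christmas = 0.75,
                                                 jan2 = 1.15,
                                                 other = 0.90),
                             dow_effects = c(Mon = 1, Tue = 1, Wed = 0.99,
                                             Thu = 0.98, Fri = 0.97,
                                             Sat = 0.85, Sun = 0.80),
                             seasonal_amplitude = 0.10,
                             trend_per_year = 0.02,
                             spatial_coeffs = list(ew = c(0.2, -0.1),
                                                   ns = c(0.15, -0.1)),
                             tmax_ref = 24) {
  if (sigma_gamma < 0 || sigma_pi < 0)
    stop_invalid("standard deviations must be >= 0")
  need <- c("standard", "christmas", "jan2", "other")
  if (!all(need %in% names(holiday_effects)))
    stop_invalid("holiday_effects must name categories: %s",
                 paste(need, collapse = ", "))
  if (any(holiday_effects <= 0))
    stop_invalid("holiday multipliers must be > 0")
  dows <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  if (!identical(names(dow_effects), dows))
    stop_invalid("dow_effects must be named Mon..Sun in order")
  if (any(dow_effects <= 0))
    stop_invalid("day-of-week multipliers must be > 0")
  if (dow_effects[["Mon"]] != 1)
    stop_invalid("the Monday reference multiplier must equal 1")
  if (!is.list(spatial_coeffs) ||
      !all(c("ew", "ns") %in% names(spatial_coeffs)))
    stop_invalid("spatial_coeffs must be a list with elements 'ew' and 'ns'")
  structure(list(alpha = alpha, gamma_star = gamma_star,
                 sigma_gamma = sigma_gamma, lambda = lambda,
                 sigma_pi = sigma_pi,
                 holiday_effects = holiday_effects[need],
                 dow_effects = dow_effects,
                 seasonal_amplitude = seasonal_amplitude,
                 trend_per_year = trend_per_year,
                 spatial_coeffs = spatial_coeffs,
                 tmax_ref = tmax_ref),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  cat(sprintf("  baseline rate         exp(alpha) = %.3g per person-day\n",
              exp(x$alpha)))
  cat(sprintf("  mean slope gamma*     %+.3f%% per 10 C\n",
              100 * (exp(10 * x$gamma_star) - 1)))
  cat(sprintf("  slope SD (per 10 C)   %.3f   modifier lambda %.3g per C\n",
              10 * x$sigma_gamma, x$lambda))
  cat(sprintf("  intercept SD          %.2f (log scale)\n", x$sigma_pi))
  cat("  holiday multipliers  ",
      paste(sprintf("%s=%.2f", names(x$holiday_effects), x$holiday_effects),
            collapse = " "), "\n")
  invisible(x)
}
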