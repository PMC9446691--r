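#' Simulation configuration
#'
#' Builds the parameter set for the synthetic multi-region daily exposure
#' panel and death-record generator. Defaults emulate the observed scale of
#' the study setting: PM2.5 ~10 ug/m3, O3 ~38 ppb, NO2 ~21 ppb, temperature
#' ~284 K, absolute humidity ~0.0073 g/cm3, cardiovascular/respiratory cause
#' shares of 34.4%/10.6%, and a planted PM2.5 effect of 0.73% per 10 ug/m3
#' on the lag 0-2 moving average.
#'
#' The unmeasured time-varying confounder U is a per-region AR(1) series.
#' It enters each pollutant on day t with loading
#' `confounder_exposure_loading` and again on day t+1 with that loading
#' times `confounder_lead_loading_ratio` (ratio 1 reproduces the
#' equal-loadings assumption under which the coefficient-difference
#' correction is exact); it enters the mortality log-rate with loading
#' `confounder_mortality_loading`.
#'
#' @param n_regions number of regions.
#' @param start_date,end_date ISO dates bounding the daily panel; the range
#'   must exceed 35 days so at least one full referent month exists.
#' @param pollutant_means named means for pm25 (ug/m3), o3 (ppb), no2 (ppb).
#' @param seasonal_amplitudes named amplitudes for the three pollutants and
#'   temperature (same units as the series).
#' @param ar1_coefficients lag-1 autocorrelations in \[0, 1) for the three
#'   pollutant deviation series and temperature noise.
#' @param cross_correlation pollutant-pollutant innovation correlation in
#'   (-1, 1).
#' @param noise_sds stationary standard deviations (>= 0) of the pollutant,
#'   temperature and humidity noise series.
#' @param temperature_mean annual mean temperature, Kelvin.
#' @param baseline_rate expected all-cause deaths per region per day.
#' @param true_log_rr named per-unit log rate ratios applied to each
#'   pollutant's lag 0-2 moving average (the planted truth).
#' @param mortality_seasonal_amplitude log-scale amplitude of the smooth
#'   seasonal mortality term (winter peak).
#' @param confounder_sd,confounder_ar1 stationary SD and autocorrelation of U.
#' @param confounder_exposure_loading scalar or named per-pollutant loading
#'   of U on exposure (exposure units per U unit).
#' @param confounder_mortality_loading loading of U on the log death rate.
#' @param confounder_lead_loading_ratio ratio of the day t+1 loading to the
#'   day t loading of U on exposure.
#' @param covariate_category_probabilities named list of probability vectors
#'   for sex, race, age_group, education, urbanicity (each sums to 1).
#' @param cause_shares probabilities splitting all-cause deaths into
#'   cardiovascular, respiratory and the remaining component.
#' @param cause_multipliers per-cause multipliers on the pollutant log rate
#'   ratios (e.g. an amplified respiratory effect).
#' @param nafld_fraction NAFLD (negative-control outcome) death rate as a
#'   fraction of `baseline_rate`; the NAFLD process shares U and the
#'   seasonal term but carries no pollutant effect.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_regions = 50L,
                       start_date = "2008-01-01",
                       end_date = "2010-12-31",
                       pollutant_means = c(pm25 = 10.4, o3 = 37.7, no2 = 21.2),
                       seasonal_amplitudes = c(pm25 = 2, o3 = 8, no2 = 4,
                                               temperature = 12),
                       ar1_coefficients = c(pm25 = 0.7, o3 = 0.7, no2 = 0.7,
                                            temperature = 0.8),
                       cross_correlation = 0.4,
                       noise_sds = c(pm25 = 4, o3 = 7, no2 = 6,
                                     temperature = 3, humidity = 8e-4),
                       temperature_mean = 284,
                       baseline_rate = 2,
                       true_log_rr = c(pm25 = log(1.0073) / 10,
                                       o3 = log(1.0020) / 10,
                                       no2 = log(1.0019) / 10),
                       mortality_seasonal_amplitude = 0.15,
                       confounder_sd = 1,
                       confounder_ar1 = 0.5,
                       confounder_exposure_loading = 0,
                       confounder_mortality_loading = 0,
                       confounder_lead_loading_ratio = 1,
                       covariate_category_probabilities = list(
                         sex = c(male = 0.469, female = 0.531),
                         race = c(white = 0.872, black = 0.108, other = 0.020),
                         age_group = c("<=45" = 0.08, "45-65" = 0.15,
                                       "65-75" = 0.20, ">=75" = 0.57),
                         education = c(lt_hs = 0.233, hs = 0.491,
                                       gt_hs = 0.276),
                         urbanicity = c(urban = 0.751, rural = 0.249)),
                       cause_shares = c(cardiovascular = 0.344,
                                        respiratory = 0.106,
                                        all_cause_component = 0.550),
                       cause_multipliers = c(cardiovascular = 1,
                                             respiratory = 1,
                                             all_cause_component = 1),
                       nafld_fraction = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    start_date = as_ccx_date(start_date, "start_date"),
    end_date = as_ccx_date(end_date, "end_date"),
    pollutant_means = assert_named_over(pollutant_means, POLLUTANTS,
                                        "pollutant_means"),
    seasonal_amplitudes = assert_named_over(
      seasonal_amplitudes, c(POLLUTANTS, "temperature"),
      "seasonal_amplitudes"),
    ar1_coefficients = assert_named_over(
      ar1_coefficients, c(POLLUTANTS, "temperature"), "ar1_coefficients"),
    cross_correlation = cross_correlation,
    noise_sds = assert_named_over(
      noise_sds, c(POLLUTANTS, "temperature", "humidity"), "noise_sds"),
    temperature_mean = temperature_mean,
    baseline_rate = baseline_rate,
    true_log_rr = assert_named_over(true_log_rr, POLLUTANTS, "true_log_rr"),
    mortality_seasonal_amplitude = mortality_seasonal_amplitude,
    confounder_sd = confounder_sd,
    confounder_ar1 = confounder_ar1,
    confounder_exposure_loading = assert_named_over(
      confounder_exposure_loading, POLLUTANTS, "confounder_exposure_loading"),
    confounder_mortality_loading = confounder_mortality_loading,
    confounder_lead_loading_ratio = confounder_lead_loading_ratio,
    covariate_category_probabilities = covariate_category_probabilities,
    cause_shares = assert_named_over(
      cause_shares, c("cardiovascular", "respiratory", "all_cause_component"),
      "cause_shares"),
    cause_multipliers = assert_named_over(
      cause_multipliers,
      c("cardiovascular", "respiratory", "all_cause_component"),
      "cause_multipliers"),
    nafld_fraction = nafld_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_regions < 1L) stop_ccx("'n_regions' must be >= 1")
  if (as.numeric(cfg$end_date - cfg$start_date) <= 35) {
    stop_ccx("'end_date' must exceed 'start_date' by more than 35 days ",
             "(at least one full referent month)")
  }
  if (any(cfg$ar1_coefficients < 0 | cfg$ar1_coefficients >= 1)) {
    stop_ccx("'ar1_coefficients' must lie in [0, 1)")
  }
  if (abs(cfg$cross_correlation) >= 1) {
    stop_ccx("'cross_correlation' must lie in (-1, 1)")
  }
  if (any(cfg$noise_sds < 0)) {
    bad <- names(cfg$noise_sds)[cfg$noise_sds < 0]
    stop_ccx(sprintf("'noise_sds': negative SD for %s",
                     paste(bad, collapse = ", ")))
  }
  if (cfg$confounder_sd < 0) stop_ccx("'confounder_sd' must be >= 0")
  if (cfg$confounder_ar1 < 0 || cfg$confounder_ar1 >= 1) {
    stop_ccx("'confounder_ar1' must lie in [0, 1)")
  }
  if (cfg$baseline_rate <= 0) stop_ccx("'baseline_rate' must be > 0")
  if (cfg$nafld_fraction < 0 || cfg$nafld_fraction > 1) {
    stop_ccx("'nafld_fraction' must lie in [0, 1]")
  }
  for (nm in names(cfg$covariate_category_probabilities)) {
    p <- cfg$covariate_category_probabilities[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop_ccx(sprintf(
        "'covariate_category_probabilities$%s' must sum to 1 (got %.15g)",
        nm, sum(p)))
    }
  }
  if (abs(sum(cfg$cause_shares) - 1) > 1e-12) {
    stop_ccx("'cause_shares' must sum to 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d regions, %s to %s (%d days)\n", x$n_regions,
              format(x$start_date), format(x$end_date),
              as.integer(x$end_date - x$start_date) + 1L))
  cat(sprintf("  baseline rate %.3g deaths/region/day; NAFLD fraction %.3g\n",
              x$baseline_rate, x$nafld_fraction))
  cat(sprintf("  planted percent increase per 10 units: %s\n",
              paste(sprintf("%s=%.2f%%", names(x$true_log_rr),
                            100 * (exp(10 * x$true_log_rr) - 1)),
                    collapse = ", ")))
  cat(sprintf("  confounder: sd %.3g, ar1 %.3g, exposure loading %s, ",
              x$confounder_sd, x$confounder_ar1,
              paste(sprintf("%.3g", x$confounder_exposure_loading),
                    collapse = "/")))
  cat(sprintf("mortality loading %.3g, lead ratio %.3g\n",
              x$confounder_mortality_loading,
              x$confounder_lead_loading_ratio))
  invisible(x)
}
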