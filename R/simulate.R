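# Stationary AR(1) matrix (n_days x n_regions): lag-1 autocorrelation `a`,
# stationary SD `s`. Innovations are supplied pre-scaled so that the
# stationary SD equals `s`; row 1 is drawn from the stationary distribution.
ar1_filter <- function(innov, a) {
  if (a == 0) return(innov)
  out <- innov
  out[1L, ] <- innov[1L, ] / sqrt(1 - a^2)
  for (t in seq_len(nrow(innov))[-1L]) {
    out[t, ] <- a * out[t - 1L, ] + innov[t, ]
  }
  out
}

seasonal_term <- function(dates, amplitude, summer_peak = FALSE) {
  doy <- as.POSIXlt(dates)$yday
  s <- cos(2 * pi * doy / 365.25)      # peaks Jan 1 (winter)
  if (summer_peak) s <- -s
  amplitude * s
}

#' Simulate a multi-region daily exposure panel
#'
#' Each pollutant series is a seasonal mean plus a stationary AR(1)
#' deviation, with pollutant-pollutant innovation correlation
#' `cross_correlation`, plus the unmeasured confounder U (AR(1)) entering
#' with loading `confounder_exposure_loading` at lag 0 and
#' `loading * confounder_lead_loading_ratio` at lag 1 (so U on the day of
#' death also appears in the next day's exposure). Pollutant values are
#' floored at 0. Temperature is an annual sinusoid (winter trough) plus
#' AR(1) noise; absolute humidity is an increasing exponential transform of
#' temperature plus noise, floored at 0.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` of class `ccx_panel` with columns date, region,
#'   pm25, o3, no2, temperature, humidity, and an attribute `"confounder"`
#'   holding the realized U by (date, region).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  dates <- seq(config$start_date, config$end_date, by = "day")
  nd <- length(dates)
  nr <- config$n_regions
  regions <- sprintf("R%03d", seq_len(nr))

  # Confounder with one extra leading day so the lag-1 loading is defined
  # from the first panel day onward.
  u_sd <- config$confounder_sd
  u_a <- config$confounder_ar1
  u_innov <- matrix(stats::rnorm((nd + 1L) * nr, sd = u_sd * sqrt(1 - u_a^2)),
                    nd + 1L, nr)
  U_ext <- ar1_filter(u_innov, u_a)
  U <- U_ext[-1L, , drop = FALSE]        # day t
  U_lag <- U_ext[-(nd + 1L), , drop = FALSE]  # day t-1

  # Cross-correlated pollutant innovations.
  rho <- config$cross_correlation
  C <- matrix(rho, 3L, 3L); diag(C) <- 1
  L <- chol(C)
  Z <- matrix(stats::rnorm(nd * nr * 3L), ncol = 3L) %*% L

  loading <- config$confounder_exposure_loading
  ratio <- config$confounder_lead_loading_ratio
  pollutant <- list()
  for (i in seq_along(POLLUTANTS)) {
    p <- POLLUTANTS[i]
    a <- config$ar1_coefficients[[p]]
    s <- config$noise_sds[[p]]
    innov <- matrix(Z[, i] * s * sqrt(1 - a^2), nd, nr)
    dev <- ar1_filter(innov, a)
    seas <- seasonal_term(dates, config$seasonal_amplitudes[[p]],
                          summer_peak = (p == "o3"))
    x <- config$pollutant_means[[p]] + seas + dev +
      loading[[p]] * (U + ratio * U_lag)
    pollutant[[p]] <- pmax(x, 0)
  }

  a_t <- config$ar1_coefficients[["temperature"]]
  s_t <- config$noise_sds[["temperature"]]
  t_innov <- matrix(stats::rnorm(nd * nr, sd = s_t * sqrt(1 - a_t^2)), nd, nr)
  temp <- config$temperature_mean -
    seasonal_term(dates, config$seasonal_amplitudes[["temperature"]]) +
    ar1_filter(t_innov, a_t)

  hum <- 0.0073 * exp(0.06 * (temp - config$temperature_mean)) +
    matrix(stats::rnorm(nd * nr, sd = config$noise_sds[["humidity"]]), nd, nr)
  hum <- pmax(hum, 0)

  panel <- data.frame(
    date = rep(dates, times = nr),
    region = rep(regions, each = nd),
    pm25 = as.vector(pollutant$pm25),
    o3 = as.vector(pollutant$o3),
    no2 = as.vector(pollutant$no2),
    temperature = as.vector(temp),
    humidity = as.vector(hum),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("ccx_panel", "data.frame")
  attr(panel, "confounder") <- data.frame(
    date = rep(dates, times = nr),
    region = rep(regions, each = nd),
    u = as.vector(U),
    stringsAsFactors = FALSE
  )
  panel
}

#' Simulate death records from an exposure panel
#'
#' Daily region counts follow a Poisson model whose log-rate is
#' `log(baseline_rate * cause_share) + seasonal + sum_p multiplier_c *
#' true_log_rr_p * (MA_{0-2}(pollutant_p) - mean_p) + mortality_loading * U`.
#' Counts are expanded to individual records with covariates drawn from the
#' configured category probabilities. NAFLD negative-control records come
#' from a parallel Poisson process that shares the seasonal and confounder
#' terms but carries no pollutant effect. The first two panel days per
#' region, where the lag 0-2 moving average is not computable, are excluded
#' (a message states how many region-days were dropped).
#'
#' @param panel a panel from [simulate_panel()] (its `"confounder"`
#'   attribute supplies U; absent that, U is taken as 0).
#' @param config the same [sim_config()] used for the panel.
#' @return a list with `deaths` (a `data.frame` of death records) and
#'   `truth` (a `sim_truth` object storing the planted log rate ratios, the
#'   realized confounder series, and the seed).
#' @export
simulate_deaths <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)

  dates <- sort(unique(panel$date))
  regions <- sort(unique(panel$region))
  nd <- length(dates); nr <- length(regions)
  if (min(dates) > config$start_date || max(dates) < config$end_date) {
    stop_ccx("panel does not cover the config date range")
  }

  conf <- attr(panel, "confounder")
  if (is.null(conf)) {
    U <- matrix(0, nd, nr)
  } else {
    U <- matrix(conf$u[order(match(conf$region, regions),
                             match(conf$date, dates))], nd, nr)
  }

  # value matrices (day x region), panel may arrive in any row order
  ord <- order(match(panel$region, regions), match(panel$date, dates))
  val <- function(col) matrix(panel[[col]][ord], nd, nr)
  ma02 <- function(m) {
    # MA over lags 0..2, defined from day 3 on
    out <- matrix(NA_real_, nd, nr)
    out[3:nd, ] <- (m[3:nd, , drop = FALSE] + m[2:(nd - 1L), , drop = FALSE] +
                      m[1:(nd - 2L), , drop = FALSE]) / 3
    out
  }

  lin <- matrix(0, nd, nr)   # planted exposure term (per-cause multipliers later)
  for (p in POLLUTANTS) {
    lin <- lin + config$true_log_rr[[p]] *
      (ma02(val(p)) - config$pollutant_means[[p]])
  }
  # Seasonal mortality at monthly resolution: the month-mean of the annual
  # cosine, constant within each calendar month, so the time-stratified
  # stratum absorbs it exactly (the design's own premise).
  s_daily <- seasonal_term(dates, config$mortality_seasonal_amplitude)
  month_key <- format(dates, "%Y-%m")
  smort <- matrix(stats::ave(s_daily, month_key), nd, nr)
  gamma_u <- config$confounder_mortality_loading

  usable <- 3:nd
  n_dropped <- (length(dates) - length(usable)) * nr
  message(sprintf(
    "simulate_deaths: excluded %d region-days with incomputable lag 0-2 moving averages",
    n_dropped))

  records <- list()
  for (cl in names(config$cause_shares)) {
    log_rate <- log(config$baseline_rate * config$cause_shares[[cl]]) +
      smort[usable, , drop = FALSE] +
      config$cause_multipliers[[cl]] * lin[usable, , drop = FALSE] +
      gamma_u * U[usable, , drop = FALSE]
    counts <- stats::rpois(length(log_rate), exp(log_rate))
    records[[cl]] <- expand_counts(counts, dates[usable], regions, cl, config)
  }
  if (config$nafld_fraction > 0) {
    log_rate <- log(config$baseline_rate * config$nafld_fraction) +
      smort[usable, , drop = FALSE] + gamma_u * U[usable, , drop = FALSE]
    counts <- stats::rpois(length(log_rate), exp(log_rate))
    records[["nafld_control"]] <- expand_counts(counts, dates[usable],
                                                regions, "nafld_control",
                                                config)
  }
  deaths <- do.call(rbind, records)
  rownames(deaths) <- NULL

  truth <- structure(list(
    true_log_rr = config$true_log_rr,
    confounder = if (is.null(conf)) NULL else conf,
    seed = config$seed
  ), class = "sim_truth")

  list(deaths = deaths, truth = truth)
}

expand_counts <- function(counts, dates, regions, cause_class, config) {
  nd <- length(dates)
  idx <- which(counts > 0L)
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(event_date = as.Date(character()),
                      region = character(), cause_class = character(),
                      sex = character(), race = character(),
                      age_group = character(), education = character(),
                      urbanicity = character(), stringsAsFactors = FALSE))
  }
  day_i <- ((idx - 1L) %% nd) + 1L
  reg_i <- ((idx - 1L) %/% nd) + 1L
  reps <- counts[idx]
  out <- data.frame(
    event_date = rep(dates[day_i], reps),
    region = rep(regions[reg_i], reps),
    cause_class = cause_class,
    stringsAsFactors = FALSE
  )
  probs <- config$covariate_category_probabilities
  for (v in c("sex", "race", "age_group", "education", "urbanicity")) {
    p <- probs[[v]]
    out[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation ground truth (seed", x$seed, ")\n")
  cat("  per-unit log rate ratios:",
      paste(sprintf("%s=%.6g", names(x$true_log_rr), x$true_log_rr),
            collapse = ", "), "\n")
  if (!is.null(x$confounder)) {
    cat(sprintf("  realized confounder series: %d (date, region) values\n",
                nrow(x$confounder)))
  }
  invisible(x)
}
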