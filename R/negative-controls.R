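# column sets for the configured model
model_columns <- function(config, pollutants = config$pollutants,
                          leads = config$include_lead_controls) {
  cols <- paste0(pollutants, "_ma")
  if (leads) cols <- c(cols, paste0(pollutants, "_lead1"))
  if ("same_day" %in% config$temperature_terms) cols <- c(cols, "temp")
  if ("same_day_squared" %in% config$temperature_terms) {
    cols <- c(cols, "temp_sq")
  }
  if ("ma_lag1_3" %in% config$temperature_terms) {
    cols <- c(cols, "temp_ma1_3")
  }
  if ("same_day" %in% config$humidity_terms) cols <- c(cols, "humidity")
  if ("ma_lag1_3" %in% config$humidity_terms) {
    cols <- c(cols, "humidity_ma1_3")
  }
  cols
}

effects_table <- function(fit, config, pollutants = config$pollutants,
                          suffix = "_ma") {
  do.call(rbind, lapply(pollutants, function(p) {
    e <- percent_increase(fit, paste0(p, suffix), config$increments[[p]])
    e$pollutant <- p
    e
  }))
}

#' Negative-exposure-control adjusted fit
#'
#' Fits the configured pollutant moving averages jointly with the lead-1
#' pollutant terms (exposure after death, which cannot be causal) and the
#' weather terms. The lead coefficients are returned separately as the
#' negative-exposure-control diagnostic: a lead estimate away from 0 flags
#' an omitted time-varying confounder correlated with exposure on adjacent
#' days.
#'
#' @param strata `ccx_strata` built with lead-1 features for every modelled
#'   pollutant.
#' @param config an [analysis_config()].
#' @return a `ccx_nec` list: `fit` (joint `ccx_fit`), `effects` (pollutant
#'   moving-average estimates), `lead_effects` (lead-1 diagnostics).
#' @export
nec_adjusted_fit <- function(strata, config) {
  stopifnot(inherits(config, "analysis_config"))
  lead_cols <- paste0(config$pollutants, "_lead1")
  missing <- setdiff(lead_cols, strata$labels)
  if (length(missing)) {
    stop_ccx(sprintf("strata lack lead-1 feature column(s): %s",
                     paste(missing, collapse = ", ")))
  }
  cols <- model_columns(config, leads = TRUE)
  fit <- clogit_fit(strata, features = cols, tol = config$tol,
                    max_iter = config$max_iter)
  structure(list(
    fit = fit,
    effects = effects_table(fit, config),
    lead_effects = effects_table(fit, config, suffix = "_lead1")
  ), class = "ccx_nec")
}

#' @export
print.ccx_nec <- function(x, ...) {
  cat("Negative-exposure-control adjusted model\n\nExposure estimates:\n")
  print(x$effects, digits = 3, row.names = FALSE)
  cat("\nLead-1 (negative exposure control) diagnostics:\n")
  print(x$lead_effects, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Coefficient-difference bias correction
#'
#' Under the assumption that an omitted time-varying confounder relates to
#' exposure identically on the day of death and the following day, the
#' unconfounded coefficient is the difference between the exposure
#' coefficient and the lead-1 coefficient from the joint fit:
#' `beta_corrected = beta_exposure - beta_lead`, with variance
#' `V_ee + V_ll - 2 V_el` taken from the joint covariance matrix. Both
#' labels must come from the same fit so the covariance term is available;
#' passing a second fit with `independent = TRUE` explicitly requests the
#' independence approximation (V_el = 0), which is flagged in the output.
#'
#' @param fit joint `ccx_fit` containing both coefficients.
#' @param exposure_label,lead_label coefficient labels.
#' @param delta reporting increment (default 10).
#' @param fit_lead optional second fit holding the lead coefficient.
#' @param independent set `TRUE` to accept the independence approximation
#'   when the coefficients come from different fits.
#' @return a `ccx_correction` list with the per-unit coefficients, the
#'   corrected coefficient and variance, and the derived `effect` row on
#'   the percent scale.
#' @export
difference_correction <- function(fit, exposure_label, lead_label,
                                  delta = 10, fit_lead = NULL,
                                  independent = FALSE) {
  stopifnot(inherits(fit, "ccx_fit"))
  if (!exposure_label %in% names(fit$coefficients)) {
    stop_ccx(sprintf("unknown coefficient label '%s'", exposure_label))
  }
  b_e <- fit$coefficients[[exposure_label]]
  v_e <- fit$vcov[exposure_label, exposure_label]
  if (is.null(fit_lead)) {
    if (!lead_label %in% names(fit$coefficients)) {
      stop_ccx(sprintf("unknown coefficient label '%s'", lead_label))
    }
    b_l <- fit$coefficients[[lead_label]]
    v_l <- fit$vcov[lead_label, lead_label]
    v_el <- fit$vcov[exposure_label, lead_label]
    approx <- FALSE
  } else {
    if (!independent) {
      stop_ccx("coefficients come from different fits, so no covariance is ",
               "available; pass independent = TRUE to request the ",
               "independence approximation explicitly")
    }
    if (!lead_label %in% names(fit_lead$coefficients)) {
      stop_ccx(sprintf("unknown coefficient label '%s'", lead_label))
    }
    b_l <- fit_lead$coefficients[[lead_label]]
    v_l <- fit_lead$vcov[lead_label, lead_label]
    v_el <- 0
    approx <- TRUE
  }
  b_c <- b_e - b_l
  var_c <- v_e + v_l - 2 * v_el
  if (var_c < 0) stop_ccx("corrected variance is negative")
  se <- sqrt(var_c)
  effect <- data.frame(
    pollutant = exposure_label,
    delta = delta,
    percent_increase = 100 * (exp(delta * b_c) - 1),
    ci_low = 100 * (exp(delta * (b_c - Z975 * se)) - 1),
    ci_high = 100 * (exp(delta * (b_c + Z975 * se)) - 1),
    p_value = 2 * stats::pnorm(-abs(b_c / se)),
    n_strata = fit$n_strata,
    n_cases = fit$n_cases,
    stringsAsFactors = FALSE
  )
  structure(list(beta_exposure = b_e, beta_lead = b_l, beta_corrected = b_c,
                 variance = var_c, independence_approximation = approx,
                 effect = effect), class = "ccx_correction")
}

#' @export
print.ccx_correction <- function(x, ...) {
  cat(sprintf(
    "Coefficient-difference correction%s\n  beta: exposure %.6g, lead %.6g, corrected %.6g (se %.3g)\n",
    if (x$independence_approximation) " [independence approximation]" else "",
    x$beta_exposure, x$beta_lead, x$beta_corrected, sqrt(x$variance)))
  print(x$effect, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Percent-scale coefficient-difference arithmetic
#'
#' Convenience audit form of [difference_correction()]: takes two printed
#' percent estimates for the same increment, converts them back to log
#' coefficients via `log(1 + p/100)`, subtracts, and re-expresses the
#' difference as a percent increase. E.g. an exposure estimate of 0.73% and
#' a lead estimate of -0.36% yield a corrected 1.09%.
#'
#' @param pct_exposure,pct_lead percent increases per the same increment.
#' @return corrected percent increase (numeric scalar).
#' @export
percent_difference_correction <- function(pct_exposure, pct_lead) {
  b_e <- log(1 + pct_exposure / 100)
  b_l <- log(1 + pct_lead / 100)
  100 * (exp(b_e - b_l) - 1)
}

#' Negative-outcome-control fit
#'
#' Runs the configured pollutant model on strata built from the
#' negative-control cause of death only (deaths the exposure should not
#' affect, e.g. NAFLD). The result is diagnostic: estimates and CIs are
#' returned for inspection along with a `consistent_with_null` flag that is
#' `TRUE` when every pollutant CI covers 0; a non-null association flags a
#' shared omitted confounder.
#'
#' @param nafld_strata `ccx_strata` from negative-control records, built
#'   with the same feature spec as the main model.
#' @param config an [analysis_config()].
#' @return a `ccx_noc` list: `fit`, `effects`, `consistent_with_null`.
#' @export
noc_fit <- function(nafld_strata, config) {
  stopifnot(inherits(config, "analysis_config"))
  S <- n_strata(nafld_strata)
  cols <- model_columns(config)
  if (S == 0L) stop_ccx("no negative-control strata supplied")
  if (S <= length(cols)) {
    stop_ccx(sprintf(
      "too few negative-control strata (%d) to fit %d features", S,
      length(cols)))
  }
  fit <- clogit_fit(nafld_strata, features = cols, tol = config$tol,
                    max_iter = config$max_iter)
  eff <- effects_table(fit, config)
  structure(list(
    fit = fit,
    effects = eff,
    consistent_with_null = all(eff$ci_low <= 0 & eff$ci_high >= 0)
  ), class = "ccx_noc")
}

#' @export
print.ccx_noc <- function(x, ...) {
  cat(sprintf("Negative-outcome-control fit (%d strata): %s\n",
              x$fit$n_strata,
              if (x$consistent_with_null) "consistent with null"
              else "NOT consistent with null"))
  print(x$effects, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Stage-1 surrogate-confounder model
#'
#' Fits a log-linear Poisson model of daily regional negative-control
#' outcome counts on the pollutant moving averages, the lead-1 terms, the
#' weather terms, and a smooth periodic seasonal basis. The fitted mean
#' per (date, region) is the surrogate for the omitted confounder used by
#' [two_stage_fit()].
#'
#' @param panel daily exposure panel.
#' @param nafld_counts either death records (the negative-control subset is
#'   aggregated to daily regional counts, zero-filled) or a data.frame with
#'   columns date, region, count.
#' @param config an [analysis_config()].
#' @param season_df even number of periodic basis columns (sin/cos pairs of
#'   the annual cycle and its harmonics).
#' @param terms `"full"` (default) or `"intercept"` (seasonal/covariate-free
#'   reference model).
#' @return a `ccx_surrogate` list: `values` (data.frame date, region,
#'   w_hat), `coefficients`, and the stage-1 model frame description.
#' @export
fit_surrogate <- function(panel, nafld_counts, config, season_df = 4L,
                          terms = c("full", "intercept")) {
  stopifnot(inherits(config, "analysis_config"))
  terms <- match.arg(terms)
  pidx <- panel_index(panel)

  if (!is.null(nafld_counts$count)) {
    counts_df <- nafld_counts
    counts_df$date <- as_ccx_date(counts_df$date)
  } else {
    recs <- nafld_counts
    if (!is.null(recs$cause_class)) {
      recs <- recs[recs$cause_class == "nafld_control", , drop = FALSE]
    }
    if (nrow(recs) == 0L) {
      stop_ccx("no negative-control outcome records to aggregate")
    }
    agg <- stats::aggregate(list(count = rep(1L, nrow(recs))),
                            by = list(date = as_ccx_date(recs$event_date),
                                      region = recs$region), FUN = sum)
    counts_df <- agg
  }

  # model grid: every (date, region) whose features are computable
  spec <- default_feature_spec(config)
  max_lag <- max(3L, vapply(config$lag_windows, max, 0L))
  lo <- max_lag + 1L
  hi <- pidx$nd - if (config$include_lead_controls) 1L else 0L
  if (hi <= lo) stop_ccx("panel too short for the surrogate model")
  di <- rep(lo:hi, times = pidx$nr)
  ri <- rep(seq_len(pidx$nr), each = hi - lo + 1L)
  feats <- compute_features(pidx, di, ri, spec)
  ok <- rowSums(is.na(feats)) == 0L
  di <- di[ok]; ri <- ri[ok]; feats <- feats[ok, , drop = FALSE]

  grid_dates <- pidx$dates[di]
  grid_regions <- pidx$regions[ri]
  key <- paste(grid_dates, grid_regions)
  cnt <- rep(0, length(key))
  mkey <- paste(counts_df$date, counts_df$region)
  hit <- match(mkey, key)
  cnt[hit[!is.na(hit)]] <- counts_df$count[!is.na(hit)]
  if (all(cnt == 0)) {
    stop_ccx("all negative-control counts are zero: degenerate outcome")
  }

  if (terms == "intercept") {
    X <- NULL
  } else {
    doy <- as.POSIXlt(grid_dates)$yday
    season <- NULL
    for (h in seq_len(max(1L, season_df %/% 2L))) {
      season <- cbind(season,
                      sin(2 * pi * h * doy / 365.25),
                      cos(2 * pi * h * doy / 365.25))
    }
    colnames(season) <- paste0(rep(c("season_sin", "season_cos"),
                                   max(1L, season_df %/% 2L)),
                               rep(seq_len(max(1L, season_df %/% 2L)),
                                   each = 2L))
    X <- cbind(feats, season)
  }

  dat <- data.frame(count = cnt)
  form <- if (is.null(X)) count ~ 1 else {
    dat <- cbind(dat, as.data.frame(X))
    stats::as.formula(paste("count ~", paste(colnames(X), collapse = " + ")))
  }
  model <- stats::glm(form, family = stats::poisson(), data = dat)
  if (!model$converged) {
    stop_ccx("stage-1 surrogate model did not converge")
  }

  structure(list(
    values = data.frame(date = grid_dates, region = grid_regions,
                        w_hat = as.numeric(stats::fitted(model)),
                        stringsAsFactors = FALSE),
    coefficients = stats::coef(model),
    vcov = stats::vcov(model),
    terms = terms,
    season_df = season_df
  ), class = "ccx_surrogate")
}

#' @export
print.ccx_surrogate <- function(x, ...) {
  cat(sprintf(
    "Stage-1 surrogate-confounder model (%s terms): %d fitted (date, region) values\n",
    x$terms, nrow(x$values)))
  cat(sprintf("  fitted mean range: %.4g .. %.4g\n", min(x$values$w_hat),
              max(x$values$w_hat)))
  invisible(x)
}

#' Two-stage double-negative-control fit
#'
#' Stage 2 of the double-negative-control estimator: refits the conditional
#' logistic model with the stage-1 fitted negative-control-outcome mean
#' (the surrogate for the omitted confounder) added as a same-day covariate.
#' By default the lead-1 negative-exposure-control terms are excluded from
#' stage 2: in the two-stage-least-squares analogy they play the instrument
#' role, and since the surrogate is a smooth function of the stage-1
#' covariates, retaining them leaves the surrogate identified only through
#' the curvature of the stage-1 link (a near-collinear design).
#' `keep_leads = TRUE` is supported for that variant. The pollutant
#' estimates from this fit are the bias-corrected "two-stage causal model"
#' results.
#'
#' @param strata `ccx_strata` with lead-1 features.
#' @param surrogate a `ccx_surrogate` covering every case/referent
#'   (date, region) in the strata.
#' @param config an [analysis_config()].
#' @param log_surrogate enter `log(w_hat)` instead of `w_hat` (surrogate
#'   scale is a modelling choice).
#' @param keep_leads retain the lead-1 terms in stage 2 (default `FALSE`;
#'   see Details).
#' @return a `ccx_two_stage` list: `fit` and pollutant `effects`.
#' @export
two_stage_fit <- function(strata, surrogate, config, log_surrogate = FALSE,
                          keep_leads = FALSE) {
  stopifnot(inherits(strata, "ccx_strata"), inherits(surrogate,
                                                     "ccx_surrogate"),
            inherits(config, "analysis_config"))
  key <- paste(strata$rows$date, strata$rows$region)
  skey <- paste(surrogate$values$date, surrogate$values$region)
  hit <- match(key, skey)
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop_ccx(sprintf(
      "surrogate does not cover %d (date, region) pair(s), e.g.: %s",
      length(miss), paste(utils::head(miss, 5L), collapse = "; ")))
  }
  w <- surrogate$values$w_hat[hit]
  if (log_surrogate) {
    if (any(w <= 0)) stop_ccx("log_surrogate requires strictly positive w_hat")
    w <- log(w)
  }

  st2 <- strata
  st2$x <- cbind(strata$x, surrogate = w)
  st2$labels <- c(strata$labels, "surrogate")

  cols <- c(model_columns(config, leads = keep_leads), "surrogate")
  # a stratum-constant surrogate carries no information; drop it from the
  # design (its contribution cancels in the conditional likelihood)
  S <- n_strata(st2)
  rng <- tapply_fast_max(w, st2$stratum, S) +
    tapply_fast_max(-w, st2$stratum, S)
  if (all(abs(rng) <= 1e-12)) {
    cols <- setdiff(cols, "surrogate")
    message("two_stage_fit: surrogate is stratum-constant and drops out ",
            "of the conditional likelihood")
  }
  fit <- clogit_fit(st2, features = cols, tol = config$tol,
                    max_iter = config$max_iter)
  structure(list(fit = fit, effects = effects_table(fit, config),
                 log_surrogate = log_surrogate, keep_leads = keep_leads),
            class = "ccx_two_stage")
}

#' @export
print.ccx_two_stage <- function(x, ...) {
  cat("Two-stage double-negative-control fit\n")
  print(x$effects, digits = 3, row.names = FALSE)
  invisible(x)
}
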