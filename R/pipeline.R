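#' Run the single-, double- and three-pollutant model families
#'
#' Fits each configured pollutant alone, every pollutant pair, and all
#' pollutants jointly (always with the configured weather terms, and with
#' lead-1 negative-exposure-control terms when enabled). The three-pollutant
#' family additionally reports the lead-coefficient diagnostics and the
#' coefficient-difference corrections.
#'
#' @param strata a `ccx_strata` carrying features for all configured
#'   pollutants.
#' @param config an [analysis_config()].
#' @return a `ccx_models` list: `effects` (one row per family x pollutant),
#'   `lead_effects`, `corrections`, and the underlying `fits`.
#' @export
run_models <- function(strata, config) {
  stopifnot(inherits(strata, "ccx_strata"), inherits(config,
                                                     "analysis_config"))
  pols <- config$pollutants
  fits <- list()
  effects <- list()

  fit_family <- function(ps, family) {
    cols <- model_columns(config, pollutants = ps)
    fit <- clogit_fit(strata, features = cols, tol = config$tol,
                      max_iter = config$max_iter)
    eff <- effects_table(fit, config, pollutants = ps)
    eff$model <- family
    eff$co_pollutants <- vapply(eff$pollutant, function(p)
      paste(setdiff(ps, p), collapse = "+"), "")
    fits[[family]] <<- fit
    effects[[family]] <<- eff
    fit
  }

  for (p in pols) fit_family(p, paste0("single_", p))
  if (length(pols) >= 2L) {
    pairs <- utils::combn(pols, 2L, simplify = FALSE)
    for (pr in pairs) fit_family(pr, paste0("double_", paste(pr,
                                                             collapse = "_")))
  }
  triple_fit <- fit_family(pols, "triple")

  lead_effects <- NULL
  corrections <- NULL
  if (config$include_lead_controls) {
    lead_effects <- effects_table(triple_fit, config, suffix = "_lead1")
    lead_effects$model <- "triple"
    corrections <- do.call(rbind, lapply(pols, function(p) {
      cr <- difference_correction(triple_fit, paste0(p, "_ma"),
                                  paste0(p, "_lead1"),
                                  delta = config$increments[[p]])
      e <- cr$effect
      e$pollutant <- p
      e$model <- "triple_corrected"
      e
    }))
  }

  eff <- do.call(rbind, effects)
  rownames(eff) <- NULL
  eff$model <- sub("_(pm25|o3|no2).*$", "", eff$model)
  structure(list(effects = eff, lead_effects = lead_effects,
                 corrections = corrections, fits = fits),
            class = "ccx_models")
}

#' @export
print.ccx_models <- function(x, ...) {
  cat("Model families\n")
  print(x$effects[, c("model", "pollutant", "co_pollutants",
                      "percent_increase", "ci_low", "ci_high", "p_value")],
        digits = 3, row.names = FALSE)
  if (!is.null(x$corrections)) {
    cat("\nCoefficient-difference corrected estimates:\n")
    print(x$corrections[, c("pollutant", "percent_increase", "ci_low",
                            "ci_high", "p_value")], digits = 3,
          row.names = FALSE)
  }
  invisible(x)
}

#' Restrict strata to low-exposure days
#'
#' A stratum is retained if and only if every one of its case and referent
#' rows has a day-level value below the threshold for every restricted
#' pollutant; rows are never dropped individually, preserving the matched
#' set. Default thresholds are the WHO air-quality-guideline daily limits
#' on the analysis units.
#'
#' @param strata a `ccx_strata`.
#' @param thresholds named positive thresholds (`Inf` disables a pollutant's
#'   restriction).
#' @return the retained `ccx_strata` subset.
#' @export
restrict_low_exposure <- function(strata,
                                  thresholds = c(pm25 = 25, o3 = 50,
                                                 no2 = 106.4)) {
  stopifnot(inherits(strata, "ccx_strata"))
  if (any(thresholds <= 0)) stop_ccx("'thresholds' must be > 0")
  unknown <- setdiff(names(thresholds), POLLUTANTS)
  if (length(unknown)) {
    stop_ccx(sprintf("unknown pollutant(s) in thresholds: %s",
                     paste(unknown, collapse = ", ")))
  }
  S <- n_strata(strata)
  keep <- rep(TRUE, S)
  for (p in names(thresholds)) {
    thr <- thresholds[[p]]
    if (!is.finite(thr)) next
    v <- strata$day_values[, p]
    v[is.na(v)] <- Inf   # a row without a day-level value cannot be verified
    mx <- tapply_fast_max(v, strata$stratum, S)
    keep <- keep & (mx < thr)
  }
  filter_strata(strata, keep)
}

#' Share of panel days below thresholds
#'
#' @param panel daily panel.
#' @param thresholds named thresholds as in [restrict_low_exposure()].
#' @return named numeric: fraction of (date, region) days strictly below
#'   each threshold.
#' @export
fraction_days_below <- function(panel, thresholds = c(pm25 = 25, o3 = 50,
                                                      no2 = 106.4)) {
  vapply(names(thresholds), function(p)
    mean(panel[[p]] < thresholds[[p]]), 0)
}

#' Cause-specific model battery
#'
#' Filters strata to one cause of death and reruns [run_models()].
#'
#' @param strata a `ccx_strata` whose `info` carries `cause_class`.
#' @param cause one of the cause classes present.
#' @param config an [analysis_config()].
#' @export
cause_specific <- function(strata, cause, config) {
  stopifnot(inherits(strata, "ccx_strata"))
  if (is.null(strata$info$cause_class)) {
    stop_ccx("strata carry no cause_class information")
  }
  keep <- strata$info$cause_class == cause
  if (!any(keep)) {
    stop_ccx(sprintf("no strata with cause_class '%s'", cause))
  }
  run_models(filter_strata(strata, keep), config)
}

#' Stratified subgroup analysis with pairwise contrasts
#'
#' Fits the three-pollutant model separately within each level of an
#' effect-modifier variable and tests every pair of levels with
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` (stratified fits are independent),
#' two-sided p.
#'
#' @param strata a `ccx_strata`.
#' @param modifier a covariate column of `strata$info` (sex, race,
#'   age_group, education, urbanicity).
#' @param config an [analysis_config()].
#' @return a `ccx_subgroups` list: per-level `effects` and pairwise
#'   `contrasts`.
#' @export
subgroup_analysis <- function(strata, modifier, config) {
  stopifnot(inherits(strata, "ccx_strata"))
  if (is.null(strata$info[[modifier]])) {
    stop_ccx(sprintf("unknown modifier '%s'; available: %s", modifier,
                     paste(setdiff(names(strata$info),
                                   c("stratum", "case_date", "region")),
                           collapse = ", ")))
  }
  levels <- sort(unique(strata$info[[modifier]]))
  cols <- model_columns(config)
  per_level <- list()
  for (lv in levels) {
    sub <- filter_strata(strata, strata$info[[modifier]] == lv)
    fit <- clogit_fit(sub, features = cols, tol = config$tol,
                      max_iter = config$max_iter)
    eff <- effects_table(fit, config)
    eff$level <- lv
    b <- fit$coefficients[paste0(config$pollutants, "_ma")]
    se <- sqrt(diag(fit$vcov)[paste0(config$pollutants, "_ma")])
    per_level[[lv]] <- list(effects = eff, beta = b, se = se)
  }
  effects <- do.call(rbind, lapply(per_level, `[[`, "effects"))
  rownames(effects) <- NULL

  contrasts <- NULL
  if (length(levels) >= 2L) {
    pairs <- utils::combn(levels, 2L, simplify = FALSE)
    contrasts <- do.call(rbind, lapply(pairs, function(pr) {
      a <- per_level[[pr[1L]]]; b <- per_level[[pr[2L]]]
      z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
      data.frame(modifier = modifier, level_1 = pr[1L], level_2 = pr[2L],
                 pollutant = config$pollutants, z = unname(z),
                 p_value = unname(2 * stats::pnorm(-abs(z))),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(modifier = modifier, effects = effects,
                 contrasts = contrasts), class = "ccx_subgroups")
}

#' @export
print.ccx_subgroups <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s\n", x$modifier))
  print(x$effects[, c("level", "pollutant", "percent_increase", "ci_low",
                      "ci_high", "n_strata")], digits = 3, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise contrasts:\n")
    print(x$contrasts, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Classify regions as urban or rural
#'
#' Urban means population density strictly above the death-weighted 25th
#' percentile of density over the study population (weights are deaths per
#' region; the percentile matches quantile type 7 on the death-expanded
#' density vector). With all densities equal the strict inequality fails
#' and every region is rural.
#'
#' @param region_densities named numeric densities per region.
#' @param deaths_per_region weights; default equal.
#' @return named character vector, `"urban"` or `"rural"`.
#' @export
classify_urbanicity <- function(region_densities,
                                deaths_per_region = NULL) {
  if (length(region_densities) == 0L) {
    stop_ccx("empty 'region_densities'")
  }
  w <- deaths_per_region %||% rep(1, length(region_densities))
  q25 <- weighted_quantile(region_densities, w, 0.25)
  out <- ifelse(region_densities > q25, "urban", "rural")
  names(out) <- names(region_densities)
  out
}

#' Sensitivity analysis: region-specific temperature terms
#'
#' Replaces each temperature feature with region-group-specific columns
#' (the interaction of temperature with region group, which is
#' stratum-constant) and re-reports the pollutant estimates. With a single
#' group this reduces exactly to the main model.
#'
#' @param strata a `ccx_strata`.
#' @param config an [analysis_config()].
#' @param groups named character vector mapping region keys to groups;
#'   default puts each region in its own group.
#' @return a `ccx_models`-like list with `fit` and `effects`.
#' @export
state_temperature_sensitivity <- function(strata, config, groups = NULL) {
  stopifnot(inherits(strata, "ccx_strata"))
  regions <- unique(strata$rows$region)
  if (is.null(groups)) groups <- stats::setNames(regions, regions)
  missing <- setdiff(regions, names(groups))
  if (length(missing)) {
    stop_ccx(sprintf("no group for region(s): %s",
                     paste(missing, collapse = ", ")))
  }
  row_group <- unname(groups[strata$rows$region])
  glevels <- sort(unique(row_group))

  temp_cols <- intersect(c("temp", "temp_sq", "temp_ma1_3"), strata$labels)
  cols <- model_columns(config)
  base_cols <- setdiff(cols, temp_cols)

  st2 <- strata
  if (length(glevels) > 1L) {
    for (tc in intersect(temp_cols, cols)) {
      for (gl in glevels) {
        nm <- paste0(tc, ":", gl)
        newcol <- strata$x[, tc] * (row_group == gl)
        st2$x <- cbind(st2$x, newcol)
        colnames(st2$x)[ncol(st2$x)] <- nm
        st2$labels <- c(st2$labels, nm)
        base_cols <- c(base_cols, nm)
      }
    }
    fit_cols <- base_cols
  } else {
    fit_cols <- cols
  }
  fit <- clogit_fit(st2, features = fit_cols, tol = config$tol,
                    max_iter = config$max_iter)
  list(fit = fit, effects = effects_table(fit, config))
}

#' Cause shares from counts
#'
#' Percentage of total deaths per cause, e.g. 1,053,304 cardiovascular of
#' 3,063,192 total gives 34.4% at one-decimal rounding.
#'
#' @param counts named cause counts.
#' @param total denominator (default `sum(counts)`).
#' @param digits rounding for the percent column (default 1).
#' @return data.frame: cause, n, percent.
#' @export
cause_shares <- function(counts, total = sum(counts), digits = 1) {
  data.frame(cause = names(counts), n = unname(counts),
             percent = round(100 * unname(counts) / total, digits),
             stringsAsFactors = FALSE)
}

#' Descriptive cohort summary
#'
#' Counts and percentages by sex, race, age group, education, urbanicity
#' and cause class, plus mean (SD) of case-day exposures when a panel is
#' supplied. An empty record set returns an empty table (no error).
#'
#' @param deaths death records.
#' @param panel optional daily panel for case-day exposure summaries.
#' @return data.frame: variable, level, n, percent, mean, sd.
#' @export
cohort_summary <- function(deaths, panel = NULL) {
  cols <- c("variable", "level", "n", "percent", "mean", "sd")
  empty <- data.frame(variable = character(), level = character(),
                      n = integer(), percent = numeric(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE)
  if (is.null(deaths) || nrow(deaths) == 0L) return(empty)
  total <- nrow(deaths)
  rows <- list()
  for (v in c("sex", "race", "age_group", "education", "urbanicity",
              "cause_class")) {
    if (is.null(deaths[[v]])) next
    tb <- table(deaths[[v]])
    rows[[v]] <- data.frame(variable = v, level = names(tb),
                            n = as.integer(tb),
                            percent = round(100 * as.integer(tb) / total, 1),
                            mean = NA_real_, sd = NA_real_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(panel)) {
    key <- paste(panel$date, panel$region)
    hit <- match(paste(as_ccx_date(deaths$event_date), deaths$region), key)
    for (p in c(POLLUTANTS, "temperature", "humidity")) {
      v <- panel[[p]][hit]
      out <- rbind(out, data.frame(
        variable = "case_day_exposure", level = p, n = sum(!is.na(v)),
        percent = NA_real_, mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out[, cols]
}

#' Run the full analysis battery
#'
#' Orchestrates the complete result set on one death/panel pair: the
#' single/double/triple pollutant families with lead diagnostics and
#' coefficient-difference corrections, the negative-outcome-control fit,
#' the stage-1 surrogate and two-stage double-negative-control fit, the
#' low-exposure restriction refit, cause-specific refits, and the cohort
#' summary. Result tables are optionally written with [write_results()].
#'
#' @param deaths death records (all causes; the negative-control cause is
#'   split off internally).
#' @param panel daily exposure panel.
#' @param config an [analysis_config()].
#' @param out_dir optional directory for delimited result tables.
#' @return a named list of result tables and fitted objects.
#' @export
run_analysis <- function(deaths, panel, config = analysis_config(),
                         out_dir = NULL) {
  spec <- default_feature_spec(config)
  main <- deaths[deaths$cause_class != "nafld_control", , drop = FALSE]
  nafld <- deaths[deaths$cause_class == "nafld_control", , drop = FALSE]

  strata <- assemble_strata(main, panel, spec)
  models <- run_models(strata, config)

  noc <- NULL; surrogate <- NULL; two_stage <- NULL
  if (nrow(nafld) > 0L) {
    nafld_strata <- assemble_strata(nafld, panel, spec)
    noc <- noc_fit(nafld_strata, config)
    surrogate <- fit_surrogate(panel, nafld, config)
    two_stage <- two_stage_fit(strata, surrogate, config)
  }

  low <- restrict_low_exposure(strata, config$low_exposure_thresholds)
  low_fit <- clogit_fit(low, features = model_columns(config),
                        tol = config$tol, max_iter = config$max_iter)
  low_effects <- effects_table(low_fit, config)
  low_effects$model <- "low_exposure"

  cause_tables <- list()
  for (cl in c("cardiovascular", "respiratory")) {
    if (any(strata$info$cause_class == cl)) {
      cs <- cause_specific(strata, cl, config)
      eff <- cs$effects[cs$effects$model == "triple", , drop = FALSE]
      eff$model <- cl
      cause_tables[[cl]] <- eff
    }
  }

  subgroups <- NULL
  if (!is.null(config$subgroup)) {
    subgroups <- subgroup_analysis(strata, config$subgroup, config)
  }

  tables <- list(
    model_families = models$effects,
    lead_diagnostics = models$lead_effects,
    corrected = models$corrections,
    low_exposure = low_effects,
    cause_specific = if (length(cause_tables)) do.call(rbind, cause_tables),
    noc = if (!is.null(noc)) noc$effects,
    two_stage = if (!is.null(two_stage)) two_stage$effects,
    cohort = cohort_summary(deaths, panel)
  )
  tables <- Filter(Negate(is.null), tables)
  if (!is.null(out_dir)) write_results(tables, out_dir)

  list(tables = tables, strata = strata, models = models, noc = noc,
       surrogate = surrogate, two_stage = two_stage,
       low_exposure_fit = low_fit,
       subgroups = subgroups)
}
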