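#' Analysis configuration
#'
#' Defines the model the pipeline fits: which pollutants enter, the lag
#' window over which each pollutant's moving average is taken (default lag
#' 0-2), the weather adjustment set (same-day temperature, its square, a
#' lag 1-3 temperature moving average; same-day humidity and its lag 1-3
#' moving average), whether lead-1 negative-exposure-control terms are
#' included, the reporting increment per pollutant (default 10 units:
#' ug/m3 for PM2.5, ppb for the gases), and the low-exposure restriction
#' thresholds (defaults are the WHO air-quality-guideline daily limits on
#' the analysis units: 25 ug/m3 PM2.5, 50 ppb O3, 106.4 ppb NO2).
#'
#' @param pollutants subset of c("pm25", "o3", "no2").
#' @param lag_windows named list of length-2 integer vectors `c(a, b)`:
#'   moving average over lags a..b per pollutant.
#' @param temperature_terms subset of c("same_day", "same_day_squared",
#'   "ma_lag1_3").
#' @param humidity_terms subset of c("same_day", "ma_lag1_3").
#' @param include_lead_controls include lead-1 pollutant terms.
#' @param increments named reporting increments (> 0).
#' @param low_exposure_thresholds named thresholds on the analysis units.
#' @param subgroup optional effect-modifier variable name.
#' @param tol Newton convergence tolerance on the max-norm of the gradient.
#' @param max_iter maximum Newton iterations.
#' @return an `analysis_config` object.
#' @export
analysis_config <- function(pollutants = c("pm25", "o3", "no2"),
                            lag_windows = list(pm25 = c(0L, 2L),
                                               o3 = c(0L, 2L),
                                               no2 = c(0L, 2L)),
                            temperature_terms = c("same_day",
                                                  "same_day_squared",
                                                  "ma_lag1_3"),
                            humidity_terms = c("same_day", "ma_lag1_3"),
                            include_lead_controls = TRUE,
                            increments = c(pm25 = 10, o3 = 10, no2 = 10),
                            low_exposure_thresholds = c(pm25 = 25, o3 = 50,
                                                        no2 = 106.4),
                            subgroup = NULL,
                            tol = 1e-8,
                            max_iter = 25L) {
  if (length(pollutants) == 0L) stop_ccx("'pollutants' must be non-empty")
  pollutants <- match.arg(pollutants, POLLUTANTS, several.ok = TRUE)
  for (p in pollutants) {
    w <- lag_windows[[p]]
    if (is.null(w) || length(w) != 2L || any(w < 0) ||
        any(w != as.integer(w)) || w[1L] > w[2L]) {
      stop_ccx(sprintf(
        "'lag_windows$%s' must be a nonnegative integer range c(a, b), a <= b",
        p))
    }
    lag_windows[[p]] <- as.integer(w)
  }
  increments <- assert_named_over(increments, pollutants, "increments")
  if (any(increments <= 0)) stop_ccx("'increments' must be > 0")
  temperature_terms <- match.arg(
    temperature_terms, c("same_day", "same_day_squared", "ma_lag1_3"),
    several.ok = TRUE)
  humidity_terms <- match.arg(humidity_terms, c("same_day", "ma_lag1_3"),
                              several.ok = TRUE)
  structure(list(
    pollutants = pollutants,
    lag_windows = lag_windows[pollutants],
    temperature_terms = temperature_terms,
    humidity_terms = humidity_terms,
    include_lead_controls = isTRUE(include_lead_controls),
    increments = increments,
    low_exposure_thresholds = low_exposure_thresholds,
    subgroup = subgroup,
    tol = tol,
    max_iter = as.integer(max_iter)
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML key-value file
#'
#' Unknown keys are an error; omitted keys take the defaults of
#' [analysis_config()].
#'
#' @param path YAML file path.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop_ccx(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  if (!is.null(y$pollutants)) y$pollutants <- unlist(y$pollutants)
  for (nm in c("increments", "low_exposure_thresholds")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(analysis_config, y)
}

#' @export
print.analysis_config <- function(x, ...) {
  win <- vapply(x$pollutants, function(p)
    sprintf("%s MA lag%d-%d", p, x$lag_windows[[p]][1L],
            x$lag_windows[[p]][2L]), "")
  cat("Analysis configuration\n")
  cat("  exposures:", paste(win, collapse = ", "), "\n")
  cat("  lead-1 negative exposure controls:",
      if (x$include_lead_controls) "included" else "excluded", "\n")
  cat("  temperature terms:", paste(x$temperature_terms, collapse = ", "),
      "\n  humidity terms:", paste(x$humidity_terms, collapse = ", "), "\n")
  invisible(x)
}
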