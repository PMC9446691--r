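#' Feature definitions for stratum design rows
#'
#' A feature spec is an ordered list of definitions, each one of:
#' * `ft_lag(var, k)` - value of `var` at date - k;
#' * `ft_ma(var, a, b)` - unweighted mean of `var` over dates
#'   (date - a) ... (date - b), a <= b;
#' * `ft_lead(var, k)` - value of `var` at date + k (negative exposure
#'   control features);
#' * `ft_square(of)` - square of another, earlier, feature.
#'
#' Labels must be unique; lag/lead offsets are nonnegative integers.
#'
#' @param ... feature definitions built with the `ft_*` constructors.
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1L]]) &&
      !inherits(defs[[1L]], "ccx_feature")) {
    defs <- defs[[1L]]
  }
  labels <- vapply(defs, function(d) d$label, "")
  if (anyDuplicated(labels)) {
    stop_ccx(sprintf("duplicate feature label(s): %s",
                     paste(unique(labels[duplicated(labels)]),
                           collapse = ", ")))
  }
  seen <- character(0)
  for (d in defs) {
    if (d$transform == "square" && !(d$of %in% seen)) {
      stop_ccx(sprintf(
        "ft_square('%s'): squared feature must be defined earlier in the spec",
        d$of))
    }
    seen <- c(seen, d$label)
  }
  structure(list(defs = defs, labels = labels), class = "feature_spec")
}

ft_def <- function(transform, var = NULL, k = NULL, a = NULL, b = NULL,
                   of = NULL, label) {
  for (off in c(k, a, b)) {
    if (off < 0 || off != as.integer(off)) {
      stop_ccx("lag/lead offsets must be nonnegative integers")
    }
  }
  structure(list(transform = transform, var = var, k = k, a = a, b = b,
                 of = of, label = label), class = "ccx_feature")
}

#' @rdname feature_spec
#' @param var source panel variable name.
#' @param k lag or lead offset in days.
#' @param a,b moving-average lag window bounds, `a <= b`.
#' @param of label of the (earlier) feature to square.
#' @param label feature label; sensible defaults are derived.
#' @export
ft_lag <- function(var, k, label = sprintf("%s_lag%d", var, k)) {
  ft_def("lag", var = var, k = as.integer(k), label = label)
}

#' @rdname feature_spec
#' @export
ft_ma <- function(var, a, b, label = sprintf("%s_ma%d_%d", var, a, b)) {
  if (a > b) stop_ccx("ft_ma: need a <= b")
  ft_def("ma", var = var, a = as.integer(a), b = as.integer(b), label = label)
}

#' @rdname feature_spec
#' @export
ft_lead <- function(var, k, label = sprintf("%s_lead%d", var, k)) {
  ft_def("lead", var = var, k = as.integer(k), label = label)
}

#' @rdname feature_spec
#' @export
ft_square <- function(of, label = sprintf("%s_sq", of)) {
  ft_def("square", of = of, label = label)
}

#' Default feature spec for an analysis configuration
#'
#' Pollutant moving averages over the configured lag windows (labelled
#' `<pollutant>_ma`), lead-1 pollutant terms (`<pollutant>_lead1`) when lead
#' controls are on, same-day temperature plus its square and a lag 1-3
#' temperature moving average, and same-day humidity plus its lag 1-3
#' moving average (per the configured term sets).
#'
#' @param config an [analysis_config()].
#' @return a `feature_spec`.
#' @export
default_feature_spec <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  defs <- list()
  for (p in config$pollutants) {
    w <- config$lag_windows[[p]]
    defs <- c(defs, list(ft_ma(p, w[1L], w[2L], label = paste0(p, "_ma"))))
  }
  if (config$include_lead_controls) {
    for (p in config$pollutants) {
      defs <- c(defs, list(ft_lead(p, 1L, label = paste0(p, "_lead1"))))
    }
  }
  if ("same_day" %in% config$temperature_terms) {
    defs <- c(defs, list(ft_lag("temperature", 0L, label = "temp")))
  }
  if ("same_day_squared" %in% config$temperature_terms) {
    defs <- c(defs, list(ft_square("temp", label = "temp_sq")))
  }
  if ("ma_lag1_3" %in% config$temperature_terms) {
    defs <- c(defs, list(ft_ma("temperature", 1L, 3L,
                               label = "temp_ma1_3")))
  }
  if ("same_day" %in% config$humidity_terms) {
    defs <- c(defs, list(ft_lag("humidity", 0L, label = "humidity")))
  }
  if ("ma_lag1_3" %in% config$humidity_terms) {
    defs <- c(defs, list(ft_ma("humidity", 1L, 3L,
                               label = "humidity_ma1_3")))
  }
  feature_spec(defs)
}

# Indexed panel: per-variable (day x region) matrices over the full
# contiguous date range; missing (date, region) cells are NA.
panel_index <- function(panel) {
  regions <- sort(unique(panel$region))
  dates <- seq(min(panel$date), max(panel$date), by = "day")
  nd <- length(dates); nr <- length(regions)
  di <- as.integer(panel$date - dates[1L]) + 1L
  ri <- match(panel$region, regions)
  vars <- setdiff(PANEL_COLUMNS, c("date", "region"))
  mats <- lapply(vars, function(v) {
    m <- matrix(NA_real_, nd, nr)
    m[cbind(di, ri)] <- panel[[v]]
    m
  })
  names(mats) <- vars
  list(regions = regions, dates = dates, nd = nd, nr = nr, mats = mats)
}

# Vectorized feature computation for aligned (date index, region index)
# row vectors; returns an n x p matrix with NA where a required day is
# outside coverage or missing from the panel.
compute_features <- function(pidx, di, ri, spec) {
  n <- length(di)
  nd <- pidx$nd
  get_at <- function(var, shift) {
    d2 <- di + shift
    ok <- !is.na(d2) & d2 >= 1L & d2 <= nd
    v <- rep(NA_real_, n)
    v[ok] <- pidx$mats[[var]][cbind(d2[ok], ri[ok])]
    v
  }
  out <- matrix(NA_real_, n, length(spec$defs),
                dimnames = list(NULL, spec$labels))
  for (j in seq_along(spec$defs)) {
    d <- spec$defs[[j]]
    out[, j] <- switch(d$transform,
      lag = get_at(d$var, -d$k),
      lead = get_at(d$var, d$k),
      ma = {
        acc <- 0
        for (k in d$a:d$b) acc <- acc + get_at(d$var, -k)
        acc / (d$b - d$a + 1L)
      },
      square = out[, d$of]^2
    )
  }
  out
}

#' Compute the feature vector for one (region, date)
#'
#' Returns the features defined by `spec` evaluated at `date` for `region`.
#' Features whose required days fall outside the panel (or on flagged gaps)
#' are `NA`, marking the vector incomplete; nothing is imputed.
#'
#' @param panel a daily panel.
#' @param region region key present in the panel.
#' @param date a `Date` (or vector of dates, recycled against `region`).
#' @param spec a [feature_spec()].
#' @return a matrix with one row per (region, date) and one column per
#'   feature label.
#' @export
build_features <- function(panel, region, date, spec) {
  pidx <- panel_index(panel)
  date <- as_ccx_date(date)
  nn <- max(length(region), length(date))
  region <- rep_len(region, nn); date <- rep_len(date, nn)
  bad <- setdiff(unique(region), pidx$regions)
  if (length(bad)) {
    stop_ccx(sprintf("region key(s) absent from panel: %s",
                     paste(bad, collapse = ", ")))
  }
  di <- as.integer(date - pidx$dates[1L]) + 1L
  di[di < 1L | di > pidx$nd] <- NA_integer_
  ri <- match(region, pidx$regions)
  compute_features(pidx, di, ri, spec)
}
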