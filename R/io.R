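PANEL_COLUMNS <- c("date", "region", "pm25", "o3", "no2", "temperature",
                   "humidity")
DEATH_COLUMNS <- c("event_date", "region", "cause_class", "sex", "race",
                   "age_group", "education", "urbanicity")

resolve_sep <- function(dialect) {
  switch(match.arg(dialect, c("comma", "tab")), comma = ",", tab = "\t")
}

read_delim_checked <- function(path, dialect, required) {
  if (!file.exists(path)) stop_ccx(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = resolve_sep(dialect),
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_ccx(sprintf("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")))
  }
  df
}

parse_numeric_col <- function(x, field, path, nonneg = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop_ccx(sprintf("%s: unparseable numeric in field '%s' at row(s) %s",
                     path, field, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (anyNA(v)) {
    stop_ccx(sprintf("%s: missing value in field '%s' at row(s) %s", path,
                     field,
                     paste(utils::head(which(is.na(v)), 5L), collapse = ", ")))
  }
  if (nonneg && any(v < 0)) {
    stop_ccx(sprintf("%s: negative value in field '%s' at row(s) %s", path,
                     field,
                     paste(utils::head(which(v < 0), 5L), collapse = ", ")))
  }
  v
}

parse_date_col <- function(x, field, path) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) {
    stop_ccx(sprintf("%s: non-ISO date in field '%s' at row(s) %s", path,
                     field, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  d
}

#' Read a daily exposure panel
#'
#' Delimited text with header columns date, region, pm25, o3, no2,
#' temperature, humidity. Dates must be ISO-8601; pollutant and humidity
#' values must be non-negative numbers; a duplicated (date, region) key is a
#' hard error. Per-region calendar gaps are permitted but flagged with a
#' warning (downstream feature construction treats missing days as
#' incomplete, never imputed).
#'
#' @param path file path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return a `ccx_panel` data.frame.
#' @export
read_panel <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  df <- read_delim_checked(path, dialect, PANEL_COLUMNS)
  if (nrow(df) == 0L) {
    out <- data.frame(date = as.Date(character()), region = character(),
                      pm25 = numeric(), o3 = numeric(), no2 = numeric(),
                      temperature = numeric(), humidity = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ccx_panel", "data.frame")
    return(out)
  }
  out <- data.frame(
    date = parse_date_col(df$date, "date", path),
    region = df$region,
    pm25 = parse_numeric_col(df$pm25, "pm25", path, nonneg = TRUE),
    o3 = parse_numeric_col(df$o3, "o3", path, nonneg = TRUE),
    no2 = parse_numeric_col(df$no2, "no2", path, nonneg = TRUE),
    temperature = parse_numeric_col(df$temperature, "temperature", path),
    humidity = parse_numeric_col(df$humidity, "humidity", path,
                                 nonneg = TRUE),
    stringsAsFactors = FALSE
  )
  key <- paste(out$date, out$region)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_ccx(sprintf("%s: duplicate (date, region) key: (%s)", path,
                     sub(" ", ", ", dup)))
  }
  for (r in unique(out$region)) {
    d <- sort(out$date[out$region == r])
    if (length(d) > 1L && any(diff(d) > 1)) {
      warning(sprintf("read_panel: region %s has calendar gaps", r),
              call. = FALSE)
    }
  }
  class(out) <- c("ccx_panel", "data.frame")
  out
}

#' Write a daily exposure panel
#' @param panel a `ccx_panel` or compatible data.frame.
#' @param path output file path.
#' @param dialect `"comma"` or `"tab"`.
#' @export
write_panel <- function(panel, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(panel)[, PANEL_COLUMNS]
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.table(df, path, sep = resolve_sep(dialect), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read death records
#'
#' Delimited text with header columns event_date, region, cause_class, sex,
#' race, age_group, education, urbanicity. `cause_class` must come from the
#' closed vocabulary (all_cause_component, cardiovascular, respiratory,
#' nafld_control); an unknown level is an error listing the allowed levels.
#'
#' @inheritParams read_panel
#' @return a data.frame of death records.
#' @export
read_deaths <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  df <- read_delim_checked(path, dialect, DEATH_COLUMNS)
  if (nrow(df) == 0L) {
    return(df[, DEATH_COLUMNS])
  }
  df$event_date <- parse_date_col(df$event_date, "event_date", path)
  bad <- which(!df$cause_class %in% CAUSE_CLASSES)
  if (length(bad)) {
    stop_ccx(sprintf(
      "%s: unknown cause_class '%s' at row %d; allowed levels: %s", path,
      df$cause_class[bad[1L]], bad[1L], paste(CAUSE_CLASSES, collapse = ", ")))
  }
  df[, DEATH_COLUMNS]
}

#' Write death records
#' @param deaths data.frame of death records.
#' @inheritParams write_panel
#' @export
write_deaths <- function(deaths, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(deaths)[, DEATH_COLUMNS]
  df$event_date <- format(df$event_date, "%Y-%m-%d")
  utils::write.table(df, path, sep = resolve_sep(dialect), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Map raw ICD-10 codes to analysis cause classes
#'
#' Codes I00-I99 map to cardiovascular and J00-J99 to respiratory; codes in
#' `nafld_codes` (configuration-supplied, e.g. "K76.0") map to
#' nafld_control; everything else becomes all_cause_component.
#'
#' @param icd character vector of ICD-10 codes.
#' @param nafld_codes character vector of codes to treat as the
#'   negative-control cause.
#' @return character vector of cause classes.
#' @export
map_icd_cause <- function(icd, nafld_codes = character()) {
  icd <- toupper(trimws(icd))
  out <- rep("all_cause_component", length(icd))
  out[icd %in% toupper(nafld_codes)] <- "nafld_control"
  letter <- substr(icd, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(icd, 2L, 3L)))
  cv <- letter == "I" & !is.na(num) & num >= 0 & num <= 99
  rp <- letter == "J" & !is.na(num) & num >= 0 & num <= 99
  out[cv & !(icd %in% toupper(nafld_codes))] <- "cardiovascular"
  out[rp & !(icd %in% toupper(nafld_codes))] <- "respiratory"
  out
}

#' Write result tables
#'
#' One delimited file per model family with the standard reporting columns
#' (model, pollutant, percent_increase, ci_low, ci_high, p_value, n_strata,
#' n_cases); extra columns present in a table are kept.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param dialect `"comma"` or `"tab"`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ext <- if (dialect == "comma") "csv" else "tsv"
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".", ext))
    utils::write.table(tables[[nm]], path, sep = resolve_sep(dialect),
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a result table written by [write_results()]
#' @param path file path.
#' @param dialect `"comma"` or `"tab"`.
#' @export
read_results <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  utils::read.table(path, header = TRUE, sep = resolve_sep(dialect),
                    stringsAsFactors = FALSE)
}

#' Write / read simulation ground truth
#'
#' The planted log rate ratios and seed go to a key-value YAML sidecar; the
#' realized confounder series goes to a companion CSV next to it.
#'
#' @param truth a `sim_truth` object.
#' @param path sidecar file path (the confounder CSV gets suffix
#'   `_confounder.csv`).
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  yaml::write_yaml(list(true_log_rr = as.list(truth$true_log_rr),
                        seed = truth$seed), path, precision = 15L)
  if (!is.null(truth$confounder)) {
    cpath <- sub("\\.[^.]*$", "", path)
    cpath <- paste0(cpath, "_confounder.csv")
    df <- truth$confounder
    df$date <- format(df$date, "%Y-%m-%d")
    utils::write.table(df, cpath, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  y <- yaml::read_yaml(path)
  cpath <- paste0(sub("\\.[^.]*$", "", path), "_confounder.csv")
  conf <- NULL
  if (file.exists(cpath)) {
    conf <- utils::read.table(cpath, header = TRUE, sep = ",",
                              stringsAsFactors = FALSE)
    conf$date <- as.Date(conf$date)
  }
  structure(list(true_log_rr = unlist(y$true_log_rr), confounder = conf,
                 seed = y$seed), class = "sim_truth")
}
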