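#' Assemble time-stratified case-crossover strata
#'
#' Builds one stratum per usable decedent: the case day plus its
#' bidirectional time-stratified referent days (same weekday, month and
#' year), each row carrying the feature vector defined by `spec` evaluated
#' on the decedent's region.
#'
#' Missing-data policy: a referent row whose feature vector is incomplete
#' is dropped individually; a stratum whose case row is incomplete is
#' dropped whole; strata left without any referent are dropped; strata in
#' which every feature is constant across rows are dropped as
#' non-informative for the conditional likelihood. All drops are counted
#' and reported via `message()`.
#'
#' @param deaths death-record data.frame (see [read_deaths()]).
#' @param panel daily exposure panel covering the deaths' regions.
#' @param spec a [feature_spec()]; see [default_feature_spec()].
#' @return a `ccx_strata` object: design matrix `x` (one row per
#'   case/referent day), case indicator `y`, integer `stratum` ids, the
#'   per-row day-level pollutant values (`day_values`, used by the
#'   low-exposure restriction), and per-stratum decedent covariates
#'   (`info`).
#' @export
assemble_strata <- function(deaths, panel, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  deaths <- as.data.frame(deaths)
  if (nrow(deaths) == 0L) stop_ccx("no death records supplied")
  pidx <- panel_index(panel)
  bad <- setdiff(unique(deaths$region), pidx$regions)
  if (length(bad)) {
    stop_ccx(sprintf("region key(s) absent from panel: %s",
                     paste(bad, collapse = ", ")))
  }

  case_dates <- as_ccx_date(deaths$event_date, "event_date")
  n <- nrow(deaths)
  refs <- select_referents_bulk(case_dates)

  sid <- c(seq_len(n), refs$stratum)
  date <- c(case_dates, refs$date)
  is_case <- c(rep(TRUE, n), rep(FALSE, nrow(refs)))
  region <- deaths$region[sid]

  di <- as.integer(date - pidx$dates[1L]) + 1L
  di[di < 1L | di > pidx$nd] <- NA_integer_
  ri <- match(region, pidx$regions)

  feats <- compute_features(pidx, di, ri, spec)
  complete <- rowSums(is.na(feats)) == 0L

  # day-level pollutant values for the low-exposure restriction
  dv <- matrix(NA_real_, length(di), 3L, dimnames = list(NULL, POLLUTANTS))
  ok <- !is.na(di)
  for (p in POLLUTANTS) {
    dv[ok, p] <- pidx$mats[[p]][cbind(di[ok], ri[ok])]
  }

  bad_case <- sid[is_case & !complete]
  n_ref_dropped <- sum(!is_case & !complete & !(sid %in% bad_case))
  keep_row <- complete & !(sid %in% bad_case)

  sid2 <- sid[keep_row]; feats <- feats[keep_row, , drop = FALSE]
  is_case2 <- is_case[keep_row]; date2 <- date[keep_row]
  region2 <- region[keep_row]; dv <- dv[keep_row, , drop = FALSE]

  tab_all <- tabulate(sid2, nbins = n)
  lone <- which(tab_all == 1L)            # case row with no referent left
  # non-informative: every feature constant across the stratum's rows
  rng <- matrix(0, n, ncol(feats))
  for (j in seq_len(ncol(feats))) {
    mx <- tapply_fast_max(feats[, j], sid2, n)
    mn <- -tapply_fast_max(-feats[, j], sid2, n)
    rng[, j] <- mx - mn
  }
  flat <- which(tab_all >= 2L & rowSums(abs(rng) > 0, na.rm = TRUE) == 0L &
                  tab_all > 0L)

  drop_sids <- union(lone, flat)
  keep2 <- !(sid2 %in% drop_sids)
  sid3 <- sid2[keep2]

  msg <- c(
    if (length(bad_case)) sprintf(
      "%d strata dropped: case day feature-incomplete", length(bad_case)),
    if (n_ref_dropped) sprintf(
      "%d referent rows dropped: feature-incomplete", n_ref_dropped),
    if (length(lone)) sprintf(
      "%d strata dropped: no referent rows left", length(lone)),
    if (length(flat)) sprintf(
      "%d strata dropped: all features constant across rows", length(flat)))
  if (length(msg)) message(paste0("assemble_strata: ",
                                  paste(msg, collapse = "; ")))

  new_id <- match(sid3, sort(unique(sid3)))
  kept_deaths <- sort(unique(sid3))
  info <- data.frame(stratum = seq_along(kept_deaths),
                     case_date = case_dates[kept_deaths],
                     region = deaths$region[kept_deaths],
                     stringsAsFactors = FALSE)
  for (v in c("cause_class", "sex", "race", "age_group", "education",
              "urbanicity")) {
    if (!is.null(deaths[[v]])) info[[v]] <- deaths[[v]][kept_deaths]
  }

  structure(list(
    x = feats[keep2, , drop = FALSE],
    y = as.integer(is_case2[keep2]),
    stratum = new_id,
    labels = spec$labels,
    rows = data.frame(stratum = new_id, date = date2[keep2],
                      region = region2[keep2], is_case = is_case2[keep2],
                      stringsAsFactors = FALSE),
    day_values = dv[keep2, , drop = FALSE],
    info = info,
    drops = list(case_incomplete = length(bad_case),
                 referents_incomplete = n_ref_dropped,
                 no_referents = length(lone),
                 non_informative = length(flat)),
    spec = spec
  ), class = "ccx_strata")
}

# per-group max over groups 1..n (NA-free input assumed); returns vector
# indexed by group id with -Inf for empty groups
tapply_fast_max <- function(x, g, n) {
  out <- rep(-Inf, n)
  o <- order(g, x)                 # last element per group is the max
  gg <- g[o]; xx <- x[o]
  last <- c(gg[-1L] != gg[-length(gg)], TRUE)
  out[gg[last]] <- xx[last]
  out
}

#' Subset strata by stratum id
#'
#' Keeps whole strata (never individual rows) and renumbers stratum ids
#' consecutively.
#'
#' @param strata a `ccx_strata` object.
#' @param keep logical or integer vector over `strata$info$stratum`.
#' @return a `ccx_strata` object.
#' @export
filter_strata <- function(strata, keep) {
  stopifnot(inherits(strata, "ccx_strata"))
  ids <- strata$info$stratum
  keep_ids <- if (is.logical(keep)) ids[keep] else intersect(ids, keep)
  if (length(keep_ids) == 0L) stop_ccx("filter_strata: no strata retained")
  row_keep <- strata$stratum %in% keep_ids
  new_id <- match(strata$stratum[row_keep], sort(keep_ids))
  info <- strata$info[ids %in% keep_ids, , drop = FALSE]
  info$stratum <- seq_len(nrow(info))
  rownames(info) <- NULL
  out <- strata
  out$x <- strata$x[row_keep, , drop = FALSE]
  out$y <- strata$y[row_keep]
  out$stratum <- new_id
  out$rows <- strata$rows[row_keep, , drop = FALSE]
  out$rows$stratum <- new_id
  rownames(out$rows) <- NULL
  out$day_values <- strata$day_values[row_keep, , drop = FALSE]
  out$info <- info
  out
}

n_strata <- function(strata) nrow(strata$info)

#' @export
print.ccx_strata <- function(x, ...) {
  cat(sprintf("Case-crossover strata: %d strata, %d rows, %d features\n",
              n_strata(x), length(x$y), ncol(x$x)))
  cat("  features:", paste(x$labels, collapse = ", "), "\n")
  dr <- unlist(x$drops)
  if (any(dr > 0)) {
    cat("  drops:", paste(sprintf("%s=%d", names(dr), dr), collapse = ", "),
        "\n")
  }
  invisible(x)
}
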