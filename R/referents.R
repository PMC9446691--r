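#' Bidirectional time-stratified referent days
#'
#' For a case day, the referents are every other day in the same calendar
#' month and year that falls on the same day of the week (ISO weekday of the
#' Gregorian calendar), both before and after the case day. Every month
#' yields 3 or 4 referents.
#'
#' @param case_date a `Date` (or ISO string) of length 1.
#' @return sorted `Date` vector of referent days, excluding the case day.
#' @export
select_referents <- function(case_date) {
  d <- as_ccx_date(case_date, "case_date")
  if (length(d) != 1L) stop_ccx("'case_date' must have length 1")
  cand <- d + 7L * c(-4L:-1L, 1L:4L)
  keep <- format(cand, "%Y-%m") == format(d, "%Y-%m")
  sort(cand[keep])
}

# Vectorized internal form: returns data.frame(stratum, date) of referents
# for a vector of case dates.
select_referents_bulk <- function(case_dates) {
  n <- length(case_dates)
  offs <- 7L * c(-4L:-1L, 1L:4L)
  cand <- rep(case_dates, each = 8L) + rep(offs, n)
  sid <- rep(seq_len(n), each = 8L)
  keep <- format(cand, "%Y-%m") == format(rep(case_dates, each = 8L), "%Y-%m")
  data.frame(stratum = sid[keep], date = cand[keep])
}
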