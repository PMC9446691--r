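POLLUTANTS <- c("pm25", "o3", "no2")

CAUSE_CLASSES <- c("all_cause_component", "cardiovascular", "respiratory",
                   "nafld_control")

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ccx <- function(...) stop(..., call. = FALSE)

assert_named_over <- function(x, names_required, field) {
  if (is.null(names(x)) && length(x) == 1L) {
    x <- stats::setNames(rep(x, length(names_required)), names_required)
  }
  if (!all(names_required %in% names(x))) {
    stop_ccx(sprintf("'%s' must be named over {%s}", field,
                     paste(names_required, collapse = ", ")))
  }
  x[names_required]
}

as_ccx_date <- function(x, field = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop_ccx(sprintf("'%s': non-ISO (YYYY-MM-DD) date at position(s) %s",
                     field, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  d
}

# Weighted quantile that reduces to stats::quantile type 7 on the vector
# expanded by integer weights (computed from cumulative weights, no expansion).
weighted_quantile <- function(x, w, p) {
  if (length(x) == 0L) stop_ccx("weighted_quantile: empty input")
  if (any(w < 0)) stop_ccx("weighted_quantile: negative weight")
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- sum(w)
  if (n <= 0) stop_ccx("weighted_quantile: total weight is zero")
  h <- (n - 1) * p + 1            # position on the expanded sorted vector
  cw <- cumsum(w)
  val_at <- function(k) x[which(cw >= k)[1L]]
  lo <- floor(h); hi <- ceiling(h)
  v_lo <- val_at(lo); v_hi <- val_at(hi)
  v_lo + (h - lo) * (v_hi - v_lo)
}
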