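Z975 <- 1.959964   # normal 97.5th percentile, Wald CI multiplier

# Extract the (X, y, g) triple for a feature subset, with validation.
design_of <- function(strata, features = NULL) {
  stopifnot(inherits(strata, "ccx_strata"))
  features <- features %||% strata$labels
  missing <- setdiff(features, strata$labels)
  if (length(missing)) {
    stop_ccx(sprintf("unknown feature label(s): %s",
                     paste(missing, collapse = ", ")))
  }
  x <- strata$x[, features, drop = FALSE]
  if (any(!is.finite(x))) {
    bad <- strata$stratum[which(rowSums(!is.finite(x)) > 0L)[1L]]
    stop_ccx(sprintf("non-finite feature value in stratum %d", bad))
  }
  list(x = x, y = strata$y, g = strata$stratum, labels = features)
}

clogit_core <- function(beta, x, y, g, gradient = FALSE, hessian = FALSE) {
  eta <- drop(x %*% beta)
  S <- max(g)
  m <- tapply_fast_max(eta, g, S)
  w <- exp(eta - m[g])
  denom <- drop(rowsum(w, g))          # groups 1..S all present
  ll <- sum(eta[y == 1L]) - sum(log(denom) + m)
  out <- list(loglik = ll)
  if (gradient || hessian) {
    p <- w / denom[g]
    out$gradient <- drop(crossprod(x, y - p))
    if (hessian) {
      xp <- x * p
      xbar <- rowsum(xp, g)
      info <- crossprod(x, xp) - crossprod(xbar)
      out$hessian <- -info
    }
  }
  out
}

#' Conditional logistic log-likelihood
#'
#' The conditional likelihood of the matched design: each stratum
#' contributes `exp(beta' x_case) / sum_j exp(beta' x_j)` over its rows.
#' Computed with per-stratum max subtraction for numerical stability.
#' Analytic gradient and Hessian (the negative observed information) are
#' returned on request.
#'
#' @param beta coefficient vector aligned to `features`.
#' @param strata a `ccx_strata` object.
#' @param features feature labels to use (default: all).
#' @param gradient,hessian also return the analytic gradient / Hessian.
#' @return a list with `loglik` and optionally `gradient`, `hessian`.
#' @export
clogit_loglik <- function(beta, strata, features = NULL, gradient = FALSE,
                          hessian = FALSE) {
  d <- design_of(strata, features)
  if (length(beta) != ncol(d$x) || any(!is.finite(beta))) {
    stop_ccx("'beta' must be finite and match the number of features")
  }
  clogit_core(beta, d$x, d$y, d$g, gradient, hessian)
}

#' Fit a conditional logistic regression
#'
#' Newton-Raphson with step-halving from `beta = 0`, which maximizes the
#' (concave) conditional likelihood. Columns are centred and scaled
#' internally (centring is a stratum-constant shift and leaves the
#' likelihood untouched; scaling conditions the information matrix) and
#' estimates are returned on the native per-unit scale. Convergence when
#' the max-norm of the standardized-scale gradient drops below `tol` or the
#' relative log-likelihood change is below 1e-10. The covariance matrix is
#' the inverse observed information at the optimum. Strata that are
#' constant on every fitted feature are excluded
#' before fitting (count reported); a rank-deficient information matrix
#' (collinear or separable design) is an error naming the offending
#' columns.
#'
#' @param strata a `ccx_strata` object.
#' @param features labels of the features to fit (default: all).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return a `ccx_fit`: coefficients, covariance `vcov`, `loglik`,
#'   `iterations`, `converged`, `n_strata`, `n_cases`, `n_rows`.
#' @export
clogit_fit <- function(strata, features = NULL, tol = 1e-8, max_iter = 25L) {
  d <- design_of(strata, features)
  x <- d$x; y <- d$y; g <- d$g
  S <- max(g)

  # exclude strata degenerate on the fitted columns
  flat <- rep(TRUE, S)
  for (j in seq_len(ncol(x))) {
    rng <- tapply_fast_max(x[, j], g, S) + tapply_fast_max(-x[, j], g, S)
    flat <- flat & (abs(rng) <= 0)
  }
  if (any(flat)) {
    message(sprintf(
      "clogit_fit: excluded %d strata constant on all fitted features",
      sum(flat)))
    keep <- !flat[g]
    x <- x[keep, , drop = FALSE]; y <- y[keep]
    g <- match(g[keep], sort(unique(g[keep])))
    S <- max(g)
  }
  if (S < ncol(x)) {
    stop_ccx(sprintf("too few informative strata (%d) for %d features",
                     S, ncol(x)))
  }

  # standardize columns internally (centering is a stratum-constant shift,
  # scaling conditions the information matrix); estimates are transformed
  # back to native per-unit scale
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")

  p <- ncol(x)
  beta <- rep(0, p)
  cur <- clogit_core(beta, x, y, g, gradient = TRUE, hessian = TRUE)
  check_full_rank(-cur$hessian, d$labels)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$gradient)) < tol) { converged <- TRUE; break }
    delta <- solve(-cur$hessian, cur$gradient)
    step <- 1
    repeat {
      cand <- beta + step * delta
      nxt <- clogit_core(cand, x, y, g, gradient = TRUE, hessian = TRUE)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik) break
      step <- step / 2
      if (step < 2^-30) {
        stop_ccx("clogit_fit: step-halving failed to improve the likelihood")
      }
    }
    rel <- abs(nxt$loglik - cur$loglik) /
      (abs(cur$loglik) + .Machine$double.eps)
    beta <- cand
    cur <- nxt
    if (max(abs(cur$gradient)) < tol || rel < 1e-10) {
      converged <- max(abs(cur$gradient)) < tol || rel < 1e-10
      break
    }
  }
  if (!converged && max(abs(cur$gradient)) < tol) converged <- TRUE
  if (!converged) {
    warning(sprintf(
      "clogit_fit: not converged after %d iterations (max |gradient| = %.3g)",
      iter, max(abs(cur$gradient))), call. = FALSE)
  }
  info <- -cur$hessian
  V <- solve(info)
  # back-transform to native units
  beta <- beta / sdev
  V <- V / tcrossprod(sdev)
  dimnames(V) <- list(d$labels, d$labels)
  structure(list(
    coefficients = stats::setNames(beta, d$labels),
    vcov = V,
    loglik = cur$loglik,
    iterations = iter,
    converged = converged,
    n_strata = S,
    n_cases = sum(y),
    n_rows = length(y),
    tol = tol
  ), class = "ccx_fit")
}

check_full_rank <- function(info, labels) {
  q <- qr(info)
  if (q$rank < ncol(info)) {
    off <- labels[q$pivot[(q$rank + 1L):ncol(info)]]
    stop_ccx(sprintf(
      "design is collinear or separable; offending feature column(s): %s",
      paste(off, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.ccx_fit <- function(x, ...) {
  cat(sprintf(
    "Conditional logistic fit: %d strata (%d rows), loglik %.4f, %s in %d iter\n",
    x$n_strata, x$n_rows, x$loglik,
    if (x$converged) "converged" else "NOT CONVERGED", x$iterations))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = x$coefficients, se = se,
                    z = x$coefficients / se)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.ccx_fit <- function(object, ...) object$coefficients

#' @export
vcov.ccx_fit <- function(object, ...) object$vcov

#' @export
logLik.ccx_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Percent increase per exposure increment
#'
#' Transforms a per-unit log-odds coefficient to the reporting scale:
#' `100 * (exp(delta * beta) - 1)` with Wald 95% CI bounds
#' `100 * (exp(delta * (beta +/- 1.959964 * se)) - 1)` and a two-sided
#' Wald p-value.
#'
#' @param fit a `ccx_fit`.
#' @param label coefficient label.
#' @param delta exposure increment (default 10 units).
#' @return one-row data.frame: pollutant, delta, percent_increase, ci_low,
#'   ci_high, p_value, n_strata, n_cases.
#' @export
percent_increase <- function(fit, label, delta = 10) {
  stopifnot(inherits(fit, "ccx_fit"))
  if (!label %in% names(fit$coefficients)) {
    stop_ccx(sprintf("unknown coefficient label '%s'", label))
  }
  b <- fit$coefficients[[label]]
  se <- sqrt(fit$vcov[label, label])
  data.frame(
    pollutant = label,
    delta = delta,
    percent_increase = 100 * (exp(delta * b) - 1),
    ci_low = 100 * (exp(delta * (b - Z975 * se)) - 1),
    ci_high = 100 * (exp(delta * (b + Z975 * se)) - 1),
    p_value = 2 * stats::pnorm(-abs(b / se)),
    n_strata = fit$n_strata,
    n_cases = fit$n_cases,
    stringsAsFactors = FALSE
  )
}
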