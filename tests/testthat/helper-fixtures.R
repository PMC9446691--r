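# Shared fixtures: small deterministic panels, random conditional-logistic
# problems wrapped as ccx_strata, and an independent brute-force likelihood.

# A small smooth + noise exposure panel (no confounder attribute).
toy_panel <- function(start = "2009-01-01", end = "2009-03-31",
                      n_regions = 2, seed = 42) {
  set.seed(seed)
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  nd <- length(dates)
  regions <- sprintf("R%03d", seq_len(n_regions))
  one <- function(base, amp, sd) {
    doy <- as.POSIXlt(dates)$yday
    pmax(base + amp * cos(2 * pi * doy / 365.25) +
           stats::rnorm(nd * n_regions, sd = sd), 0)
  }
  panel <- data.frame(
    date = rep(dates, times = n_regions),
    region = rep(regions, each = nd),
    pm25 = one(10, 2, 3),
    o3 = one(38, -8, 5),
    no2 = one(21, 4, 4),
    temperature = 284 - 12 * cos(2 * pi * as.POSIXlt(rep(dates,
      n_regions))$yday / 365.25) + stats::rnorm(nd * n_regions, sd = 2),
    humidity = pmax(0.0073 + stats::rnorm(nd * n_regions, sd = 5e-4), 0),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("ccx_panel", "data.frame")
  panel
}

# Death records placed away from panel edges so all features are computable.
toy_deaths <- function(panel, n = 60, seed = 7,
                       causes = c("all_cause_component", "cardiovascular",
                                  "respiratory")) {
  set.seed(seed)
  dates <- sort(unique(panel$date))
  ok <- dates[(dates >= dates[1] + 7) & (dates <= dates[length(dates)] - 7)]
  data.frame(
    event_date = sample(ok, n, replace = TRUE),
    region = sample(unique(panel$region), n, replace = TRUE),
    cause_class = sample(causes, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    race = sample(c("white", "black", "other"), n, replace = TRUE),
    age_group = sample(c("<65", "65-74", "75+"), n, replace = TRUE),
    education = sample(c("<=hs", ">hs"), n, replace = TRUE),
    urbanicity = sample(c("urban", "rural"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Wrap an (x, y, g) triple as a minimal ccx_strata object.
strata_from_xyg <- function(x, y, g, labels = colnames(x)) {
  colnames(x) <- labels
  n <- length(y)
  base <- as.Date("2009-01-06")
  structure(list(
    x = x, y = as.integer(y), stratum = as.integer(g), labels = labels,
    rows = data.frame(stratum = as.integer(g), date = base + seq_len(n),
                      region = "R001", is_case = y == 1L,
                      stringsAsFactors = FALSE),
    day_values = matrix(NA_real_, n, 3,
                        dimnames = list(NULL, c("pm25", "o3", "no2"))),
    info = data.frame(stratum = seq_len(max(g)),
                      case_date = base + seq_len(max(g)), region = "R001",
                      stringsAsFactors = FALSE),
    drops = list(), spec = NULL
  ), class = "ccx_strata")
}

# Random small matched problem: one case per stratum, continuous features.
# A random draw can be separable (the conditional MLE diverges), where the
# fit-vs-oracle comparison is ill-posed; such draws are rejected
# deterministically and redrawn from an offset seed. A separable problem
# slipping through would still blow up the oracle comparison, so the
# rejection cannot mask a defect.
make_clogit_problem <- function(seed, max_strata = 20, max_rows = 4,
                                max_features = 3) {
  repeat {
    set.seed(seed)
    S <- sample(8:max_strata, 1)
    p <- sample(seq_len(max_features), 1)
    sizes <- sample(2:max_rows, S, replace = TRUE)
    g <- rep(seq_len(S), sizes)
    n <- length(g)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    beta0 <- stats::rnorm(p, sd = 0.5)
    y <- integer(n)
    for (s in seq_len(S)) {
      idx <- which(g == s)
      pr <- exp(x[idx, , drop = FALSE] %*% beta0)
      y[sample(idx, 1, prob = pr / sum(pr))] <- 1L
    }
    strata <- strata_from_xyg(x, y, g)
    probe <- suppressWarnings(clogit_fit(strata, max_iter = 200))
    if (probe$converged && max(abs(coef(probe))) < 6) {
      return(list(x = x, y = y, g = g, strata = strata))
    }
    seed <- seed + 100000L
  }
}

# Independent brute-force conditional log-likelihood: direct per-stratum
# probability, no shared code with the package internals.
bf_loglik <- function(beta, x, y, g) {
  ll <- 0
  for (s in unique(g)) {
    idx <- which(g == s)
    num <- exp(sum(x[idx[y[idx] == 1L], ] * beta))
    den <- sum(exp(x[idx, , drop = FALSE] %*% beta))
    ll <- ll + log(num / den)
  }
  ll
}

# Central-difference gradient of a scalar function.
num_grad <- function(f, beta, h = 1e-5) {
  vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, 0)
}

# Reference fit: exact conditional logistic likelihood via survival::coxph
# (what survival::clogit wraps).
survival_fit <- function(x, y, g) {
  dat <- as.data.frame(x)
  dat$y <- y
  dat$g <- g
  dat$time <- rep(1, length(y))
  form <- stats::as.formula(paste(
    "survival::Surv(time, y) ~", paste(colnames(x), collapse = " + "),
    "+ survival::strata(g)"))
  survival::coxph(form, data = dat, method = "exact")
}
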