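# A confounded small simulation reused across the negative-control tests.
nc_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_regions = 4, start_date = "2009-01-01",
                      end_date = "2009-12-31", baseline_rate = 2,
                      nafld_fraction = 0.3,
                      confounder_exposure_loading = c(pm25 = 1.5, o3 = 0,
                                                      no2 = 0),
                      confounder_mortality_loading = 0.2,
                      confounder_ar1 = 0.9, seed = 2024)
    panel <- simulate_panel(cfg)
    deaths <- suppressMessages(simulate_deaths(panel, cfg))$deaths
    ac <- analysis_config()
    spec <- default_feature_spec(ac)
    main <- deaths[deaths$cause_class != "nafld_control", ]
    nafld <- deaths[deaths$cause_class == "nafld_control", ]
    st <- suppressMessages(assemble_strata(main, panel, spec))
    nst <- suppressMessages(assemble_strata(nafld, panel, spec))
    cache <<- list(cfg = cfg, panel = panel, ac = ac, spec = spec,
                   strata = st, nafld_strata = nst, nafld = nafld)
    cache
  }
})

test_that("nec_adjusted_fit returns joint exposure and lead estimates", {
  s <- nc_sim()
  nec <- nec_adjusted_fit(s$strata, s$ac)
  expect_s3_class(nec, "ccx_nec")
  expect_equal(nec$effects$pollutant, c("pm25", "o3", "no2"))
  expect_equal(nec$lead_effects$pollutant, c("pm25", "o3", "no2"))
  expect_true(all(paste0(c("pm25", "o3", "no2"), "_lead1") %in%
                    names(coef(nec$fit))))

  # without lead features in the strata the call must fail loudly
  ac0 <- analysis_config(include_lead_controls = FALSE)
  spec0 <- default_feature_spec(ac0)
  st0 <- suppressMessages(assemble_strata(
    toy_deaths(s$panel, n = 30), s$panel, spec0))
  expect_error(nec_adjusted_fit(st0, s$ac), "lack lead-1 feature")
})

test_that("difference_correction reproduces the joint-covariance algebra", {
  s <- nc_sim()
  fit <- nec_adjusted_fit(s$strata, s$ac)$fit
  cr <- difference_correction(fit, "pm25_ma", "pm25_lead1")
  b <- coef(fit); V <- vcov(fit)
  expect_equal(cr$beta_corrected, b[["pm25_ma"]] - b[["pm25_lead1"]])
  expect_equal(cr$variance,
               V["pm25_ma", "pm25_ma"] + V["pm25_lead1", "pm25_lead1"] -
                 2 * V["pm25_ma", "pm25_lead1"])
  expect_false(cr$independence_approximation)
  expect_equal(cr$effect$percent_increase,
               100 * (exp(10 * cr$beta_corrected) - 1))

  expect_error(difference_correction(fit, "pm25_ma", "nope"),
               "unknown coefficient label")
  # separate fits require an explicit independence approximation
  expect_error(difference_correction(fit, "pm25_ma", "pm25_lead1",
                                     fit_lead = fit),
               "independent = TRUE")
  cr2 <- difference_correction(fit, "pm25_ma", "pm25_lead1", fit_lead = fit,
                               independent = TRUE)
  expect_true(cr2$independence_approximation)
  expect_equal(cr2$beta_corrected, cr$beta_corrected)
  expect_equal(cr2$variance,
               V["pm25_ma", "pm25_ma"] + V["pm25_lead1", "pm25_lead1"])
})

test_that("percent_difference_correction inverts the percent transform", {
  # direct check of the log-scale arithmetic on arbitrary values
  expect_equal(percent_difference_correction(5, 2),
               100 * (exp(log(1.05) - log(1.02)) - 1))
  expect_equal(percent_difference_correction(3, 0), 3)
})

test_that("noc_fit flags non-null negative-control outcomes", {
  s <- nc_sim()
  noc <- noc_fit(s$nafld_strata, s$ac)
  expect_s3_class(noc, "ccx_noc")
  expect_equal(nrow(noc$effects), 3L)
  expect_identical(noc$consistent_with_null,
                   all(noc$effects$ci_low <= 0 & noc$effects$ci_high >= 0))
  few <- filter_strata(s$nafld_strata, s$nafld_strata$info$stratum <= 5)
  expect_error(noc_fit(few, s$ac), "too few negative-control strata")
})

test_that("fit_surrogate covers the analysis grid with finite nonneg values", {
  s <- nc_sim()
  sur <- fit_surrogate(s$panel, s$nafld, s$ac)
  expect_s3_class(sur, "ccx_surrogate")
  expect_true(all(is.finite(sur$values$w_hat) & sur$values$w_hat >= 0))
  # covers every (date, region) used by the strata
  key <- paste(s$strata$rows$date, s$strata$rows$region)
  skey <- paste(sur$values$date, sur$values$region)
  expect_true(all(key %in% skey))

  # an intercept-only stage-1 model fits the overall mean count
  counts <- stats::aggregate(
    list(count = rep(1L, nrow(s$nafld))),
    by = list(date = s$nafld$event_date, region = s$nafld$region), FUN = sum)
  sur0 <- fit_surrogate(s$panel, counts, s$ac, terms = "intercept")
  grid_keys <- paste(sur0$values$date, sur0$values$region)
  cnt <- rep(0, length(grid_keys))
  hit <- match(paste(counts$date, counts$region), grid_keys)
  cnt[hit[!is.na(hit)]] <- counts$count[!is.na(hit)]
  expect_equal(unique(round(sur0$values$w_hat, 10)), round(mean(cnt), 10))

  zero <- counts
  zero$count <- 0L
  expect_error(fit_surrogate(s$panel, zero, s$ac), "all negative-control")
  expect_error(fit_surrogate(s$panel, s$nafld[0, ], s$ac),
               "no negative-control outcome records")
})

test_that("two_stage_fit adds the surrogate and validates coverage", {
  s <- nc_sim()
  sur <- fit_surrogate(s$panel, s$nafld, s$ac)
  ts <- two_stage_fit(s$strata, sur, s$ac)
  expect_s3_class(ts, "ccx_two_stage")
  expect_true("surrogate" %in% names(coef(ts$fit)))
  expect_false(any(grepl("_lead1", names(coef(ts$fit)))))
  ts2 <- two_stage_fit(s$strata, sur, s$ac, keep_leads = TRUE)
  expect_true(any(grepl("_lead1", names(coef(ts2$fit)))))

  # truncated surrogate coverage is an error naming missing pairs
  short <- sur
  short$values <- sur$values[sur$values$date > min(sur$values$date) + 40, ]
  expect_error(two_stage_fit(s$strata, short, s$ac),
               "surrogate does not cover")

  # a stratum-constant surrogate drops out with a message
  flat <- sur
  flat$values$w_hat <- 1
  expect_message(ts3 <- two_stage_fit(s$strata, flat, s$ac),
                 "stratum-constant")
  expect_false("surrogate" %in% names(coef(ts3$fit)))

  neg <- sur
  neg$values$w_hat <- neg$values$w_hat - max(neg$values$w_hat)
  expect_error(two_stage_fit(s$strata, neg, s$ac, log_surrogate = TRUE),
               "strictly positive")
})
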