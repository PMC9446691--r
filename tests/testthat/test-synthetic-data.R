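small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_regions = 2, start_date = "2009-01-01",
         end_date = "2009-04-30", seed = 99),
    list(...))
  do.call(sim_config, args)
}

test_that("sim_config validation catches bad parameters by name", {
  expect_error(small_cfg(noise_sds = c(pm25 = -1, o3 = 7, no2 = 6,
                                       temperature = 3, humidity = 8e-4)),
               "negative SD for pm25")
  expect_error(small_cfg(ar1_coefficients = c(pm25 = 1, o3 = 0.7, no2 = 0.7,
                                              temperature = 0.8)),
               "\\[0, 1\\)")
  expect_error(small_cfg(cross_correlation = 1), "\\(-1, 1\\)")
  expect_error(small_cfg(cause_shares = c(cardiovascular = 0.5,
                                          respiratory = 0.5,
                                          all_cause_component = 0.5)),
               "sum to 1")
  expect_error(small_cfg(end_date = "2009-01-20"), "35 days")
  expect_error(small_cfg(baseline_rate = 0), "> 0")
  expect_error(small_cfg(nafld_fraction = 1.5), "\\[0, 1\\]")
  expect_error(small_cfg(confounder_ar1 = 1), "confounder_ar1")
  probs <- list(sex = c(male = 0.6, female = 0.5),
                race = c(white = 1), age_group = c(a = 1),
                education = c(e = 1), urbanicity = c(urban = 1))
  expect_error(small_cfg(covariate_category_probabilities = probs),
               "sex")
})

test_that("zero SDs are allowed (noise-free degenerate series)", {
  cfg <- small_cfg(noise_sds = c(pm25 = 0, o3 = 0, no2 = 0,
                                 temperature = 0, humidity = 0))
  panel <- simulate_panel(cfg)
  # noise-free series are identical across regions
  a <- panel[panel$region == "R001", "pm25"]
  b <- panel[panel$region == "R002", "pm25"]
  expect_equal(a, b)
})

test_that("simulation is reproducible by seed", {
  p1 <- simulate_panel(small_cfg())
  p2 <- simulate_panel(small_cfg())
  expect_identical(p1, p2)
  p3 <- simulate_panel(small_cfg(seed = 100))
  expect_false(isTRUE(all.equal(p1$pm25, p3$pm25)))

  d1 <- suppressMessages(simulate_deaths(p1, small_cfg()))
  d2 <- suppressMessages(simulate_deaths(p2, small_cfg()))
  expect_identical(d1$deaths, d2$deaths)
})

test_that("panel has the documented shape and physical floors", {
  cfg <- small_cfg()
  panel <- simulate_panel(cfg)
  dates <- seq(cfg$start_date, cfg$end_date, by = "day")
  expect_equal(nrow(panel), length(dates) * cfg$n_regions)
  expect_named(panel, c("date", "region", "pm25", "o3", "no2",
                        "temperature", "humidity"))
  expect_true(all(panel$pm25 >= 0 & panel$o3 >= 0 & panel$no2 >= 0 &
                    panel$humidity >= 0))
  conf <- attr(panel, "confounder")
  expect_equal(nrow(conf), nrow(panel))
  # default loading is zero, so U is simulated but not injected
  expect_true(stats::sd(conf$u) > 0)
})

test_that("simulate_deaths excludes edge days and labels causes", {
  cfg <- small_cfg(nafld_fraction = 0.05)
  panel <- simulate_panel(cfg)
  expect_message(out <- simulate_deaths(panel, cfg),
                 "excluded 4 region-days")
  deaths <- out$deaths
  expect_true(all(deaths$event_date >= cfg$start_date + 2))
  expect_true(all(deaths$cause_class %in%
                    c("all_cause_component", "cardiovascular",
                      "respiratory", "nafld_control")))
  expect_true(any(deaths$cause_class == "nafld_control"))
  expect_true(all(c("sex", "race", "age_group", "education",
                    "urbanicity") %in% names(deaths)))
  expect_true(all(deaths$sex %in%
                    names(cfg$covariate_category_probabilities$sex)))
  expect_s3_class(out$truth, "sim_truth")
  expect_equal(out$truth$true_log_rr, cfg$true_log_rr)

  cfg0 <- small_cfg(nafld_fraction = 0)
  d0 <- suppressMessages(simulate_deaths(simulate_panel(cfg0), cfg0))$deaths
  expect_false(any(d0$cause_class == "nafld_control"))
})

test_that("death counts track the configured baseline rate", {
  cfg <- small_cfg(baseline_rate = 3, mortality_seasonal_amplitude = 0)
  deaths <- suppressMessages(simulate_deaths(simulate_panel(cfg), cfg))$deaths
  days <- as.numeric(cfg$end_date - cfg$start_date) + 1 - 2
  n_expect <- 3 * days * cfg$n_regions
  n_main <- sum(deaths$cause_class != "nafld_control")
  expect_lt(abs(n_main - n_expect) / sqrt(n_expect), 4)
})

test_that("confounder loading propagates into exposure and mortality", {
  cfg <- small_cfg(confounder_exposure_loading = c(pm25 = 2, o3 = 0, no2 = 0),
                   confounder_mortality_loading = 0.3, confounder_ar1 = 0.8)
  panel <- simulate_panel(cfg)
  conf <- attr(panel, "confounder")
  expect_gt(stats::cor(panel$pm25, conf$u), 0.2)
  expect_lt(abs(stats::cor(panel$o3, conf$u)), 0.2)
})
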