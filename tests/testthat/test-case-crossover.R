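test_that("select_referents keeps weekday, month, year and drops the case", {
  d <- as.Date("2009-02-15")   # a Sunday
  refs <- select_referents(d)
  expect_true(all(format(refs, "%u") == format(d, "%u")))
  expect_true(all(format(refs, "%Y-%m") == format(d, "%Y-%m")))
  expect_false(d %in% refs)
  expect_equal(refs, as.Date(c("2009-02-01", "2009-02-08", "2009-02-22")))

  # a month with five occurrences of the weekday gives 4 referents
  refs5 <- select_referents("2009-03-02")   # Mondays: 2,9,16,23,30 March
  expect_equal(length(refs5), 4L)
})

test_that("select_referents input validation", {
  expect_error(select_referents(c("2009-01-01", "2009-01-02")), "length 1")
  expect_error(select_referents("01/02/2009"), "non-ISO")
})

test_that("bulk referent selection agrees with the scalar form", {
  dates <- as.Date("2010-06-01") + 0:40
  bulk <- casecrossnc:::select_referents_bulk(dates)
  for (i in c(1, 15, 30, 41)) {
    expect_equal(sort(bulk$date[bulk$stratum == i]),
                 select_referents(dates[i]))
  }
})

test_that("assemble_strata builds one stratum per usable death", {
  panel <- toy_panel()
  deaths <- toy_deaths(panel, n = 40)
  spec <- default_feature_spec(analysis_config())
  st <- suppressMessages(assemble_strata(deaths, panel, spec))

  expect_s3_class(st, "ccx_strata")
  # one case row per stratum
  expect_true(all(tapply(st$y, st$stratum, sum) == 1L))
  # referent rows share the case's weekday and month
  for (s in unique(st$stratum)[1:5]) {
    ds <- st$rows$date[st$rows$stratum == s]
    expect_equal(length(unique(format(ds, "%u"))), 1L)
    expect_equal(length(unique(format(ds, "%Y-%m"))), 1L)
  }
  # feature values match a direct computation for one case row
  r1 <- st$rows[st$rows$is_case & st$rows$stratum == 1, ]
  sub <- panel[panel$region == r1$region, ]
  ma <- mean(sub$pm25[sub$date %in% (r1$date - 0:2)])
  expect_equal(unname(st$x[st$rows$is_case & st$rows$stratum == 1,
                           "pm25_ma"]), ma)
})

test_that("assemble_strata drop policy", {
  panel <- toy_panel()
  spec <- default_feature_spec(analysis_config())
  d0 <- sort(unique(panel$date))[1]

  # case on the first panel day: lag features incomputable, stratum dropped
  deaths_bad <- data.frame(event_date = d0, region = "R001",
                           cause_class = "cardiovascular",
                           stringsAsFactors = FALSE)
  deaths_ok <- toy_deaths(panel, n = 10)
  expect_message(
    st <- assemble_strata(rbind(deaths_bad, deaths_ok[names(deaths_bad)]),
                          panel, spec),
    "case day feature-incomplete")
  expect_equal(casecrossnc:::n_strata(st), 10L)

  # a referent day outside panel coverage is dropped individually: take a
  # case 1 week after panel start whose earliest referent precedes coverage
  d_edge <- d0 + 7
  if (format(d_edge, "%Y-%m") == format(d0, "%Y-%m")) {
    deaths_edge <- data.frame(event_date = d_edge, region = "R001",
                              cause_class = "cardiovascular",
                              stringsAsFactors = FALSE)
    st2 <- suppressMessages(assemble_strata(deaths_edge, panel, spec))
    n_enumerated <- length(select_referents(d_edge))
    expect_lt(sum(st2$stratum == 1) - 1L, n_enumerated)
  }

  expect_error(assemble_strata(deaths_ok[0, ], panel, spec),
               "no death records")
  deaths_reg <- deaths_ok
  deaths_reg$region[1] <- "R999"
  expect_error(assemble_strata(deaths_reg, panel, spec),
               "absent from panel")
})

test_that("filter_strata keeps whole strata and renumbers", {
  panel <- toy_panel()
  deaths <- toy_deaths(panel, n = 30)
  spec <- default_feature_spec(analysis_config())
  st <- suppressMessages(assemble_strata(deaths, panel, spec))
  keep <- st$info$stratum %in% c(2, 5, 9)
  sub <- filter_strata(st, keep)
  expect_equal(casecrossnc:::n_strata(sub), 3L)
  expect_equal(sort(unique(sub$stratum)), 1:3)
  expect_equal(sum(sub$y), 3L)
  expect_error(filter_strata(st, rep(FALSE, casecrossnc:::n_strata(st))),
               "no strata retained")
})

test_that("restrict_low_exposure keeps a stratum only if every row passes", {
  panel <- toy_panel()
  deaths <- toy_deaths(panel, n = 30)
  spec <- default_feature_spec(analysis_config())
  st <- suppressMessages(assemble_strata(deaths, panel, spec))
  thr <- c(pm25 = stats::median(panel$pm25), o3 = Inf, no2 = Inf)
  low <- restrict_low_exposure(st, thr)
  mx <- tapply(st$day_values[, "pm25"], st$stratum, max)
  expect_equal(casecrossnc:::n_strata(low), sum(mx < thr[["pm25"]]))
  # retained strata really are below threshold on every row
  expect_true(all(low$day_values[, "pm25"] < thr[["pm25"]]))
  expect_error(restrict_low_exposure(st, c(pm25 = -1)), "must be > 0")
  expect_error(restrict_low_exposure(st, c(lead = 5)), "unknown pollutant")
})

test_that("fraction_days_below computes strict-threshold shares", {
  panel <- toy_panel()
  fr <- fraction_days_below(panel, c(pm25 = 10, o3 = 40, no2 = 106.4))
  expect_equal(fr[["pm25"]], mean(panel$pm25 < 10))
  expect_equal(fr[["no2"]], mean(panel$no2 < 106.4))
})
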