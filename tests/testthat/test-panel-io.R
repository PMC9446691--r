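test_that("panel roundtrips through comma and tab dialects", {
  panel <- toy_panel(end = "2009-01-31")
  for (dialect in c("comma", "tab")) {
    path <- tempfile(fileext = if (dialect == "comma") ".csv" else ".tsv")
    write_panel(panel, path, dialect)
    back <- read_panel(path, dialect)
    expect_s3_class(back, "ccx_panel")
    expect_equal(back$date, panel$date)
    expect_equal(back$region, panel$region)
    expect_equal(back$pm25, panel$pm25, tolerance = 1e-12)
    expect_equal(back$humidity, panel$humidity, tolerance = 1e-12)
    unlink(path)
  }
})

test_that("panel parse errors carry file, field and row information", {
  panel <- toy_panel(end = "2009-01-15")
  path <- tempfile(fileext = ".csv")

  write_panel(rbind(panel, panel[1, ]), path)
  expect_error(read_panel(path), "duplicate \\(date, region\\) key")

  bad <- panel
  bad$pm25[3] <- -2
  write_panel(bad, path)
  expect_error(read_panel(path), "negative value in field 'pm25' at row\\(s\\) 3")

  bad <- panel
  bad$o3 <- as.character(bad$o3)
  bad$o3[5] <- "n/a"
  df <- as.data.frame(bad)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "unparseable numeric in field 'o3' at row\\(s\\) 5")

  df <- as.data.frame(panel)
  df$date <- format(df$date, "%d/%m/%Y")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(path), "non-ISO date in field 'date'")

  utils::write.table(data.frame(a = 1), path, sep = ",", row.names = FALSE)
  expect_error(read_panel(path), "missing column\\(s\\)")
  expect_error(read_panel(tempfile()), "file not found")
  unlink(path)
})

test_that("calendar gaps warn but do not error", {
  panel <- toy_panel(end = "2009-01-31")
  gap <- panel[!(panel$date == as.Date("2009-01-15") &
                   panel$region == "R001"), ]
  path <- tempfile(fileext = ".csv")
  write_panel(gap, path)
  expect_warning(back <- read_panel(path), "calendar gaps")
  expect_equal(nrow(back), nrow(gap))
  unlink(path)
})

test_that("death records roundtrip and enforce the cause vocabulary", {
  panel <- toy_panel(end = "2009-02-28")
  deaths <- toy_deaths(panel, n = 25)
  path <- tempfile(fileext = ".csv")
  write_deaths(deaths, path)
  back <- read_deaths(path)
  expect_equal(back$event_date, deaths$event_date)
  expect_equal(back$cause_class, deaths$cause_class)

  bad <- deaths
  bad$cause_class[2] <- "homicide"
  write_deaths(bad, path)
  expect_error(read_deaths(path),
               "unknown cause_class 'homicide' at row 2.*all_cause_component")
  unlink(path)
})

test_that("map_icd_cause implements the chapter ranges and overrides", {
  expect_equal(
    map_icd_cause(c("I21", "i50.9", "J45", "J99", "K76.0", "C34", "X42"),
                  nafld_codes = "K76.0"),
    c("cardiovascular", "cardiovascular", "respiratory", "respiratory",
      "nafld_control", "all_cause_component", "all_cause_component"))
  # nafld override wins over a chapter match
  expect_equal(map_icd_cause("I99", nafld_codes = "I99"), "nafld_control")
  expect_equal(map_icd_cause(character()), character())
})

test_that("result tables and simulation truth roundtrip", {
  tbl <- data.frame(model = "triple", pollutant = "pm25",
                    percent_increase = 0.73, ci_low = 0.38, ci_high = 1.08,
                    p_value = 1e-4, n_strata = 100L, n_cases = 100L,
                    stringsAsFactors = FALSE)
  dir <- tempfile()
  paths <- write_results(list(model_families = tbl), dir)
  back <- read_results(file.path(dir, "model_families.csv"))
  expect_equal(back$percent_increase, tbl$percent_increase)
  expect_equal(back$model, tbl$model)

  cfg <- sim_config(n_regions = 2, start_date = "2009-01-01",
                    end_date = "2009-03-31", seed = 3)
  panel <- simulate_panel(cfg)
  truth <- suppressMessages(simulate_deaths(panel, cfg))$truth
  tpath <- file.path(dir, "truth.yaml")
  write_sim_truth(truth, tpath)
  back <- read_sim_truth(tpath)
  expect_equal(back$true_log_rr, truth$true_log_rr, tolerance = 1e-12)
  expect_equal(back$seed, truth$seed)
  expect_equal(nrow(back$confounder), nrow(truth$confounder))
  expect_equal(back$confounder$u, truth$confounder$u, tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})
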