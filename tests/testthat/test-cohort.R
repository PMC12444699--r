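test_that("the cohort rule admits and rejects records per the definition", {
  ## direct asthma primary with exacerbation code
  expect_true(classify_admission(
    admission_record("J45.901", has_exacerbation_or_status = TRUE)))
  ## missing exacerbation / status asthmaticus code
  expect_false(classify_admission(
    admission_record("J45.901", has_exacerbation_or_status = FALSE)))
  ## exclusion condition
  expect_false(classify_admission(
    admission_record("J45.901", has_exacerbation_or_status = TRUE,
                     exclusion_flags = "cystic_fibrosis")))
  ## secondary pathway: respiratory primary + secondary J45
  expect_true(classify_admission(
    admission_record("J18.9", secondary_codes = "J45.909",
                     has_exacerbation_or_status = TRUE)))
  ## non-respiratory primary does not qualify even with secondary J45
  expect_false(classify_admission(
    admission_record("K21.9", secondary_codes = "J45.909",
                     has_exacerbation_or_status = TRUE)))
  ## respiratory primary without any secondary J45
  expect_false(classify_admission(
    admission_record("J18.9", secondary_codes = "R05",
                     has_exacerbation_or_status = TRUE)))
})

test_that("flipping any single required condition flips a qualifying record", {
  base <- admission_record("J20.9", secondary_codes = c("I10", "J45.42"),
                           has_exacerbation_or_status = TRUE)
  expect_true(classify_admission(base))
  variants <- list(
    admission_record("K21.9", secondary_codes = c("I10", "J45.42"),
                     has_exacerbation_or_status = TRUE),
    admission_record("J20.9", secondary_codes = "I10",
                     has_exacerbation_or_status = TRUE),
    admission_record("J20.9", secondary_codes = c("I10", "J45.42"),
                     has_exacerbation_or_status = FALSE),
    admission_record("J20.9", secondary_codes = c("I10", "J45.42"),
                     has_exacerbation_or_status = TRUE,
                     exclusion_flags = "sickle_cell"))
  for (v in variants) expect_false(classify_admission(v))
})

test_that("malformed codes and unknown exclusions are rejected", {
  expect_error(admission_record("45.901"), "malformed")
  expect_error(admission_record("J45.901", secondary_codes = "bad code"),
               "malformed")
  expect_error(admission_record("J45.901", exclusion_flags = "asthma"),
               "unknown")
})

test_that("record aggregation matches a brute-force per-day filter", {
  start <- as.Date("2022-05-01"); end <- as.Date("2022-05-10")
  expect_equal(aggregate_records_to_series(list(), start, end)$count,
               rep(0L, 10))

  ## 3 qualifying + 2 non-qualifying records on one day
  recs <- c(
    lapply(1:3, function(i)
      admission_record("J45.901", has_exacerbation_or_status = TRUE,
                       date = "2022-05-03")),
    list(admission_record("J45.901", has_exacerbation_or_status = FALSE,
                          date = "2022-05-03"),
         admission_record("K21.9", secondary_codes = "J45.2",
                          has_exacerbation_or_status = TRUE,
                          date = "2022-05-03")))
  s <- aggregate_records_to_series(recs, start, end)
  expect_equal(s$count[s$date == as.Date("2022-05-03")], 3L)
  expect_equal(sum(s$count), 3L)

  ## randomized records against an explicit loop oracle
  set.seed(141)
  pool_primary <- c("J45.21", "J18.9", "K21.9", "R05", "J45.901")
  rand_recs <- lapply(1:60, function(i)
    admission_record(sample(pool_primary, 1),
                     secondary_codes = if (runif(1) < 0.5) "J45.909" else character(0),
                     has_exacerbation_or_status = runif(1) < 0.7,
                     exclusion_flags = if (runif(1) < 0.15) "tracheostomy" else character(0),
                     date = start + sample(0:9, 1)))
  s2 <- aggregate_records_to_series(rand_recs, start, end)
  for (d in seq(start, end, by = "day")) {
    manual <- sum(vapply(rand_recs, function(r)
      r$date == d && classify_admission(r), TRUE))
    expect_equal(s2$count[s2$date == d], manual)
  }
  expect_error(aggregate_records_to_series(
    list(admission_record("J45.1", has_exacerbation_or_status = TRUE,
                          date = "2023-01-01")), start, end), "outside")
})

test_that("series CSV round-trips and reports structured errors", {
  s <- toy_series(25L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, path)
  expect_equal(read_admissions_csv(path), s)

  ## duplicate date named in the error
  writeLines(c("date,count", "2022-01-01,2", "2022-01-01,3"), path)
  expect_error(read_admissions_csv(path), "2022-01-01")

  ## gaps error unless filled
  writeLines(c("date,count", "2022-01-01,2", "2022-01-04,3"), path)
  expect_error(read_admissions_csv(path), "gap")
  expect_message(filled <- read_admissions_csv(path, fill_zeros = TRUE), "filled")
  expect_equal(filled$count, c(2L, 0L, 0L, 3L))

  writeLines(c("date,count", "2022-01-01,-2"), path)
  expect_error(read_admissions_csv(path), "negative")
  writeLines(c("date,count", "not-a-date,2"), path)
  expect_error(read_admissions_csv(path), "row 1")

  ## forecast CSV round-trip
  fc <- data.frame(date = as.Date("2023-01-01") + 0:1, model = "arima",
                   point = c(1.5, 2.5), lo95 = c(0, 1), hi95 = c(3, 4))
  write_forecasts_csv(fc, path)
  back <- read.csv(path)
  expect_equal(back$point, fc$point)
  expect_equal(as.Date(back$date), fc$date)
})

test_that("run configurations round-trip through YAML", {
  cfg <- run_config(
    generator = asthma_scenario_config(seed = 5L),
    models = list(arima = arima_spec(0, 1, 2), ets = "auto",
                  prophet = prophet_spec(n_changepoints = 10L)),
    backtest = backtest_config(2L, "2023-01-01", "2023-03-31",
                               models = list(arima = arima_spec(0, 1, 2))),
    risk_percentile = 0.95, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)

  expect_equal(back$seed, 9L)
  expect_equal(back$risk_percentile, 0.95)
  g <- back$generator
  expect_s3_class(g, "generator_config")
  expect_equal(g$baseline_log_intensity, cfg$generator$baseline_log_intensity)
  expect_equal(unname(g$annual_fourier), unname(cfg$generator$annual_fourier))
  expect_equal(g$dow_effects, cfg$generator$dow_effects)
  expect_equal(as.Date(g$pandemic_window), cfg$generator$pandemic_window)
  expect_s3_class(back$models$arima, "arima_spec")
  expect_identical(back$models$ets, "auto")
  expect_equal(back$models$prophet$n_changepoints, 10L)
  expect_equal(back$backtest$validation_start, as.Date("2023-01-01"))

  ## a regenerated series from the round-tripped generator is identical
  s1 <- generate_series(cfg$generator, "2020-01-01", "2020-06-30")
  s2 <- generate_series(g, "2020-01-01", "2020-06-30")
  expect_identical(s1$count, s2$count)
})
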