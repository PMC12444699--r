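fast_models <- function() {
  list(arima = arima_spec(0, 1, 1),
       ets = ets_spec("none", "none"),
       prophet = prophet_spec(n_changepoints = 5L, weekly_order = 2L,
                              yearly_order = 0L, uncertainty_samples = 100L))
}

test_that("a constant series is forecast at its constant by every model", {
  s <- daily_series(as.Date("2021-06-01") + 0:(430 - 1), rep(3L, 430))
  cfg <- backtest_config(1L, "2022-06-01", "2022-06-10",
                         models = fast_models(), seed = 4L)
  bt <- run_backtest(s, cfg)
  expect_true(all(abs(bt$point - 3) < 1e-6))
  expect_true(all(bt$lo95 - 1e-6 <= 3 & 3 <= bt$hi95 + 1e-6))
  expect_true(all(bt$actual == 3L))
})

test_that("row counts, contiguity and the training threshold are recorded", {
  s <- scenario_series(seed = 2L)
  cfg <- backtest_config(1L, "2023-03-01", "2023-03-20",
                         models = fast_models(), seed = 11L)
  bt <- run_backtest(s, cfg)
  expect_equal(nrow(bt), 4L * 20L)  # 3 members + ensemble
  expect_setequal(unique(bt$model), c("arima", "ets", "prophet", "ensemble"))
  expect_equal(sort(unique(bt$date)), seq(as.Date("2023-03-01"), by = "day",
                                          length.out = 20L))
  expect_true(attr(bt, "observed_threshold") >= 1L)
  ## the ensemble rows are the member means
  for (d in unique(bt$date)) {
    day <- bt[bt$date == d, ]
    expect_equal(day$point[day$model == "ensemble"],
                 mean(day$point[day$model != "ensemble"]), tolerance = 1e-10)
  }
})

test_that("backtests are deterministic under a fixed seed", {
  s <- scenario_series(seed = 3L)
  cfg <- backtest_config(1L, "2023-05-01", "2023-05-08",
                         models = fast_models(), seed = 21L)
  a <- run_backtest(s, cfg)
  b <- run_backtest(s, cfg)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("temporal causality: future observations never affect a forecast", {
  s <- scenario_series(seed = 4L)
  cfg <- backtest_config(1L, "2023-04-01", "2023-04-08",
                         models = fast_models(), seed = 31L)
  base <- run_backtest(s, cfg)

  ## inject a large spike on validation day 5 and later
  mutated <- s
  spike <- mutated$date >= as.Date("2023-04-05")
  mutated$count[spike] <- mutated$count[spike] + 50L
  mut <- run_backtest(daily_series(mutated$date, mutated$count), cfg)

  upto <- base$date <= as.Date("2023-04-05")  # forecasts made from data < d
  expect_equal(base$point[upto], mut$point[upto], tolerance = 1e-10)
  expect_equal(base$lo95[upto], mut$lo95[upto], tolerance = 1e-10)
  ## and the later forecasts do react
  after <- base$date > as.Date("2023-04-05")
  expect_gt(max(abs(base$point[after] - mut$point[after])), 0.5)
})

test_that("window policies and structure selection work end to end", {
  s <- scenario_series(seed = 5L)
  cfg365 <- backtest_config(2L, "2023-02-01", "2023-02-05",
                            models = list(arima = "auto"),
                            window_policy = "sliding-365", seed = 41L)
  bt <- run_backtest(s, cfg365)
  expect_equal(nrow(bt), 5L)
  expect_s3_class(bt, "backtest_result")

  cfg_exp <- backtest_config(1L, "2023-02-01", "2023-02-05",
                             models = list(ets = "auto"),
                             window_policy = "expanding", seed = 42L)
  expect_equal(nrow(run_backtest(s, cfg_exp)), 5L)

  expect_error(run_backtest(series_window(s, "2022-06-01", NULL),
                            backtest_config(2L, "2023-01-01", "2023-01-05",
                                            models = fast_models())),
               "training window")
})

test_that("the sweep yields one metrics row per window length per model", {
  s <- scenario_series(seed = 6L)
  tab <- sweep_training_windows(s, years_list = 1:2,
                                validation_start = "2023-06-01",
                                validation_end = "2023-06-21",
                                models = list(arima = arima_spec(0, 1, 1),
                                              ets = ets_spec("none", "none")),
                                seed = 51L)
  expect_equal(nrow(tab), 2L * 3L)  # 2 windows x (2 members + ensemble)
  expect_true(all(c("window_years", "model", "mape", "coverage", "auc",
                    "sensitivity", "specificity", "ppv", "npv") %in% names(tab)))
  tab2 <- sweep_training_windows(s, years_list = 1:2,
                                 validation_start = "2023-06-01",
                                 validation_end = "2023-06-21",
                                 models = list(arima = arima_spec(0, 1, 1),
                                               ets = ets_spec("none", "none")),
                                 seed = 51L)
  expect_equal(tab, tab2)
})

test_that("pandemic-era split configurations match the stated periods", {
  s <- scenario_series(seed = 7L)
  splits <- covid_splits(s, models = fast_models())
  expect_named(splits, c("pre_pandemic", "pandemic_era", "two_year_validation"))
  expect_equal(format(splits$pre_pandemic$validation_start, "%Y"), "2019")
  expect_equal(format(splits$pre_pandemic$validation_end, "%Y"), "2019")
  expect_equal(splits$pre_pandemic$training_years, 3L)
  expect_equal(format(splits$pandemic_era$validation_start), "2023-01-01")
  expect_equal(splits$pandemic_era$training_years, 3L)
  expect_equal(format(splits$two_year_validation$validation_start), "2022-01-01")
  expect_equal(format(splits$two_year_validation$validation_end), "2023-12-31")
  expect_equal(splits$two_year_validation$training_years, 6L)
  ## validation windows never overlap their training windows
  for (cfg in splits) {
    train_end <- cfg$validation_start - 1L
    expect_lt(as.integer(train_end), as.integer(cfg$validation_start))
  }
  expect_error(covid_splits(series_window(s, "2017-01-01", NULL)), "span")
})
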