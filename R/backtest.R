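#' Configure a rolling-origin backtest
#'
#' Describes one validation experiment: an initial training window of
#' `training_years` calendar years ending the day before `validation_start`,
#' a window policy for the daily re-estimation, and the model set. Model
#' structure (ARIMA orders, ETS form) is chosen once on the initial training
#' window when a model entry is `"auto"`; parameters are re-estimated every
#' `refit_cadence` days on the policy window, and a one-step-ahead forecast
#' is recorded for every validation day. No future observation ever enters
#' a fit.
#'
#' The window policies resolve an ambiguity inherent in sweeping training
#' lengths while updating daily: `"sliding-full"` (default) re-estimates on
#' a sliding window of the initial training length; `"sliding-365"` always
#' uses the most recent 365 days; `"expanding"` uses all history from the
#' initial training start.
#'
#' @param training_years initial training window length in calendar years
#'   (1..7 in the usual sweep).
#' @param validation_start,validation_end first and last validation dates.
#' @param models named list; each element is an [arima_spec()],
#'   [ets_spec()] or [prophet_spec()], or the string `"auto"` (structure
#'   selection on the initial window; names must then be `arima`, `ets` or
#'   `prophet`).
#' @param window_policy `"sliding-full"`, `"sliding-365"`, or `"expanding"`.
#' @param refit_cadence days between parameter re-estimations (default 1 =
#'   daily refit).
#' @param include_ensemble add the member-averaging ensemble row when at
#'   least two models are present.
#' @param seed integer seed driving all stochastic interval simulation.
#' @param max_fail_frac abort when more than this fraction of refits fails
#'   for any model (failed refits fall back to the previous parameters).
#' @return an object of class `backtest_config`.
#' @export
backtest_config <- function(training_years,
                            validation_start, validation_end,
                            models = list(arima = arima_spec(0, 1, 2),
                                          ets = ets_spec("none", "additive", 7L),
                                          prophet = prophet_spec()),
                            window_policy = c("sliding-full", "sliding-365",
                                              "expanding"),
                            refit_cadence = 1L,
                            include_ensemble = length(models) >= 2L,
                            seed = 1L, max_fail_frac = 0.2) {
  window_policy <- match.arg(window_policy)
  validation_start <- as.Date(validation_start)
  validation_end <- as.Date(validation_end)
  if (validation_start > validation_end) stop("empty validation period")
  if (training_years < 1L) stop("`training_years` must be >= 1")
  if (is.null(names(models)) || any(names(models) == ""))
    stop("`models` must be a named list")
  for (nm in names(models)) {
    m <- models[[nm]]
    if (identical(m, "auto") && !nm %in% c("arima", "ets", "prophet"))
      stop("\"auto\" models must be named arima, ets or prophet")
    if (!identical(m, "auto") &&
        !inherits(m, c("arima_spec", "ets_spec", "prophet_spec")))
      stop("model `", nm, "` is not a recognised spec")
  }
  structure(list(training_years = as.integer(training_years),
                 validation_start = validation_start,
                 validation_end = validation_end,
                 models = models, window_policy = window_policy,
                 refit_cadence = as.integer(refit_cadence),
                 include_ensemble = isTRUE(include_ensemble),
                 seed = as.integer(seed), max_fail_frac = max_fail_frac),
            class = "backtest_config")
}

#' @export
print.backtest_config <- function(x, ...) {
  cat(sprintf("<backtest_config> train %dy, validate %s..%s, policy %s, cadence %dd\n",
              x$training_years, format(x$validation_start),
              format(x$validation_end), x$window_policy, x$refit_cadence))
  cat("  models:", paste(names(x$models), collapse = ", "),
      if (x$include_ensemble) "+ ensemble" else "", "\n")
  invisible(x)
}

shift_years <- function(date, years) {
  seq(date, by = paste0(-years, " years"), length.out = 2L)[2L]
}

model_kind <- function(nm, spec) {
  if (inherits(spec, "arima_spec")) "arima"
  else if (inherits(spec, "ets_spec")) "ets"
  else if (inherits(spec, "prophet_spec")) "prophet"
  else nm
}

## parameter re-estimation on one window, with warm start and fallback
refit_model <- function(kind, spec, window, prev) {
  fit <- switch(kind,
    arima = try(fit_arima(window, spec,
                          init = if (!is.null(prev)) coef(prev)), silent = TRUE),
    ets = try(fit_ets(window, spec,
                      start = if (!is.null(prev)) prev$par), silent = TRUE),
    prophet = try(fit_prophet(window, spec,
                              warm = if (!is.null(prev)) prev$beta_scaled),
                  silent = TRUE))
  if (inherits(fit, "try-error")) NULL else fit
}

#' Run a rolling-origin one-step-ahead backtest
#'
#' For each validation day `d`, each model is re-estimated on the policy
#' window ending at `d - 1` (warm-started from the previous day's
#' parameters; a failed refit falls back to those parameters with a
#' warning counted against `max_fail_frac`) and its one-step forecast for
#' `d` is recorded next to the actual count. Deterministic for a fixed
#' config seed.
#'
#' @param series an `adm_series` covering the initial training window and
#'   the validation period.
#' @param config a [backtest_config()].
#' @return an object of class `backtest_result`: a data frame with columns
#'   `date`, `model`, `actual`, `point`, `lo95`, `hi95`, one row per model
#'   per validation day, with attributes `config`, `train_start`,
#'   `observed_threshold` (95th-percentile threshold of the initial
#'   training window) and `n_refit_failures`.
#' @export
run_backtest <- function(series, config) {
  stopifnot(inherits(series, "adm_series"), inherits(config, "backtest_config"))
  train_start <- shift_years(config$validation_start, config$training_years)
  if (series$date[1L] > train_start)
    stop("series starts ", format(series$date[1L]), " but the ",
         config$training_years, "-year training window needs ", format(train_start))
  if (series$date[nrow(series)] < config$validation_end)
    stop("series ends before the validation period")
  L <- as.integer(config$validation_start - train_start)  # window length in days

  val_dates <- seq(config$validation_start, config$validation_end, by = "day")
  counts <- setNames(series$count, format(series$date))
  specs <- config$models
  kinds <- vapply(names(specs), function(nm)
    model_kind(nm, specs[[nm]]), "")

  ## one-off structure selection on the initial training window
  init_window <- series_window(series, train_start, config$validation_start - 1L)
  for (nm in names(specs)) {
    if (identical(specs[[nm]], "auto")) {
      specs[[nm]] <- switch(kinds[[nm]],
        arima = select_arima(init_window),
        ets = select_ets(init_window),
        prophet = prophet_spec())
    }
    ## yearly Fourier terms need two full years of history; on shorter
    ## windows the trend and weekly terms carry the model
    eff_L <- if (config$window_policy == "sliding-365") 365L else L
    if (kinds[[nm]] == "prophet" && eff_L < 2L * 366L &&
        specs[[nm]]$yearly_order > 0L) {
      specs[[nm]]$yearly_order <- 0L
      message("training window under two years: yearly seasonality ",
              "disabled for model `", nm, "`")
    }
  }

  fits <- setNames(vector("list", length(specs)), names(specs))
  ages <- setNames(rep(0L, length(specs)), names(specs))  # days since refit
  fails <- setNames(rep(0L, length(specs)), names(specs))
  out <- vector("list", length(val_dates))

  for (i in seq_along(val_dates)) {
    d <- val_dates[i]
    w_start <- switch(config$window_policy,
                      "sliding-full" = d - L,
                      "sliding-365" = d - 365L,
                      "expanding" = train_start)
    window <- series_window(series, w_start, d - 1L)
    refit_today <- ((i - 1L) %% config$refit_cadence) == 0L

    member_fc <- list()
    for (nm in names(specs)) {
      if (refit_today || is.null(fits[[nm]])) {
        newfit <- refit_model(kinds[[nm]], specs[[nm]], window, fits[[nm]])
        if (is.null(newfit)) {
          fails[[nm]] <- fails[[nm]] + 1L
          ages[[nm]] <- ages[[nm]] + 1L
          if (is.null(fits[[nm]]))
            stop("model `", nm, "` failed on the first refit")
          if (fails[[nm]] / length(val_dates) > config$max_fail_frac)
            stop("model `", nm, "` failed on more than ",
                 round(100 * config$max_fail_frac), "% of refits")
        } else {
          fits[[nm]] <- newfit
          ages[[nm]] <- 0L
        }
      } else {
        ages[[nm]] <- ages[[nm]] + 1L
      }
      h <- ages[[nm]] + 1L   # stale fits forecast further ahead
      fc <- if (kinds[[nm]] == "prophet")
        forecast(fits[[nm]], h = h, seed = (config$seed %% 100000L) * 10000L + i)
      else forecast(fits[[nm]], h = h)
      member_fc[[nm]] <- fc[h, , drop = FALSE]
      member_fc[[nm]]$date <- d
      member_fc[[nm]]$model <- nm
    }
    if (config$include_ensemble && length(member_fc) >= 2L)
      member_fc$ensemble <- ensemble_forecast(unname(member_fc))
    day_rows <- do.call(rbind, lapply(member_fc, as.data.frame))
    day_rows$actual <- counts[[format(d)]]
    out[[i]] <- day_rows
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("date", "model", "actual", "point", "lo95", "hi95")]
  if (sum(fails) > 0L)
    warning(sum(fails), " refit(s) fell back to previous parameters")
  structure(res, class = c("backtest_result", "data.frame"),
            config = config, train_start = train_start,
            observed_threshold = observed_threshold(init_window),
            n_refit_failures = fails)
}

#' @export
print.backtest_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<backtest_result> %d rows (%d models x %d days), train %dy policy %s\n",
              nrow(x), length(unique(x$model)), length(unique(x$date)),
              cfg$training_years, cfg$window_policy))
  cat(sprintf("  observed high-risk threshold of training window: %d\n",
              attr(x, "observed_threshold")))
  invisible(x)
}

#' Sweep training-history window lengths
#'
#' Runs one backtest per training-window length and assembles the
#' per-model evaluation rows of [metrics_report()] into a single table
#' (one row per window length per model), using each backtest's own
#' initial-training-window exceedance threshold for the high-risk labels.
#' A window length whose backtest fails contributes no rows but does not
#' abort the sweep.
#'
#' @param series an `adm_series`.
#' @param years_list integer vector of training window lengths (years).
#' @param validation_start,validation_end validation period dates.
#' @param models model list as in [backtest_config()].
#' @param seed integer seed.
#' @param ... further arguments to [backtest_config()].
#' @return a data frame; attribute `failures` names failed window lengths.
#' @export
sweep_training_windows <- function(series, years_list, validation_start,
                                   validation_end, models, seed = 1L, ...) {
  rows <- list(); failures <- character(0)
  for (yrs in years_list) {
    cfg <- backtest_config(yrs, validation_start, validation_end,
                           models = models, seed = seed, ...)
    bt <- try(run_backtest(series, cfg), silent = TRUE)
    if (inherits(bt, "try-error")) {
      failures <- c(failures, as.character(yrs))
      warning("window of ", yrs, " year(s) failed: ",
              attr(bt, "condition")$message)
      next
    }
    mr <- metrics_report(bt, attr(bt, "observed_threshold"))
    rows[[as.character(yrs)]] <- cbind(window_years = yrs, mr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Pandemic-era backtest configurations
#'
#' Returns the three standard robustness configurations for a series
#' spanning 2016-2023: models formulated on 2016-2018 and evaluated on
#' 2019 (pre-pandemic), formulated on 2020-2022 and evaluated on 2023
#' (pandemic era), and a two-year validation 2022-2023 trained on
#' 2016-2021.
#'
#' @param series an `adm_series` spanning 2016-01-01..2023-12-31.
#' @param models model list as in [backtest_config()].
#' @param seed integer seed.
#' @return named list of three `backtest_config`s: `pre_pandemic`,
#'   `pandemic_era`, `two_year_validation`.
#' @export
covid_splits <- function(series, models = list(arima = arima_spec(0, 1, 2),
                                               ets = ets_spec("none", "additive", 7L),
                                               prophet = prophet_spec()),
                         seed = 1L) {
  stopifnot(inherits(series, "adm_series"))
  if (series$date[1L] > as.Date("2016-01-01") ||
      series$date[nrow(series)] < as.Date("2023-12-31"))
    stop("series must span 2016-01-01..2023-12-31")
  list(
    pre_pandemic = backtest_config(3L, "2019-01-01", "2019-12-31",
                                   models = models, seed = seed),
    pandemic_era = backtest_config(3L, "2023-01-01", "2023-12-31",
                                   models = models, seed = seed),
    two_year_validation = backtest_config(6L, "2022-01-01", "2023-12-31",
                                          models = models, seed = seed))
}
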