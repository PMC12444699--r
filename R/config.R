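#' Serialize and restore a run configuration
#'
#' A run configuration bundles the generator settings, the model
#' specifications, the backtest layout, the risk percentile and the metric
#' policies into one declarative YAML document that round-trips unchanged,
#' so a whole validation experiment can be archived or repeated from a
#' single file.
#'
#' @param generator a [generator_config()] (or `NULL`).
#' @param models named list of model specs as in [backtest_config()].
#' @param backtest a [backtest_config()] (or `NULL`); its own model list is
#'   replaced by `models` when both are given.
#' @param risk_percentile exceedance percentile for the alert calibration.
#' @param mape_zero_policy zero-count-day policy, see [mape()].
#' @param seed top-level integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = NULL, models = NULL, backtest = NULL,
                       risk_percentile = 0.95,
                       mape_zero_policy = "exclude-zero-actuals", seed = 1L) {
  structure(list(generator = generator, models = models, backtest = backtest,
                 risk_percentile = risk_percentile,
                 mape_zero_policy = mape_zero_policy, seed = as.integer(seed)),
            class = "run_config")
}

spec_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  out <- lapply(unclass(x), function(v) {
    if (inherits(v, "Date")) format(v)
    else if (is.matrix(v)) list(.matrix_rows = apply(v, 1L, as.list))
    else v
  })
  out$.class <- class(x)[1L]
  out
}

list_to_spec <- function(x) {
  if (is.null(x)) return(NULL)
  cls <- x$.class
  x$.class <- NULL
  x <- lapply(x, function(v) {
    if (is.list(v) && !is.null(v$.matrix_rows))
      do.call(rbind, lapply(v$.matrix_rows, unlist))
    else if (is.character(v) && all(grepl("^\\d{4}-\\d{2}-\\d{2}$", v)))
      as.Date(v)
    else if (is.list(v)) unlist(v)
    else v
  })
  ## numeric fields yaml may have read as integer-ish remain comparable
  structure(x, class = cls)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  doc <- list(
    generator = spec_to_list(config$generator),
    models = if (!is.null(config$models))
      lapply(config$models, function(m) if (identical(m, "auto")) "auto" else spec_to_list(m)),
    backtest = spec_to_list(config$backtest),
    risk_percentile = config$risk_percentile,
    mape_zero_policy = config$mape_zero_policy,
    seed = config$seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  models <- if (!is.null(doc$models))
    lapply(doc$models, function(m) if (identical(m, "auto")) "auto" else list_to_spec(m))
  bt <- list_to_spec(doc$backtest)
  if (!is.null(bt)) {
    bt$models <- models
    bt$validation_start <- as.Date(bt$validation_start)
    bt$validation_end <- as.Date(bt$validation_end)
  }
  run_config(generator = list_to_spec(doc$generator), models = models,
             backtest = bt, risk_percentile = doc$risk_percentile,
             mape_zero_policy = doc$mape_zero_policy, seed = doc$seed)
}

#' Published descriptive totals of the emulated admission series
#'
#' Aggregate descriptive statistics reported for the eight-year (2016-2023)
#' pediatric asthma admission series that the synthetic generator emulates:
#' monthly totals, day-of-week totals, the grand total, and the zero-day
#' count. Used for calendar-arithmetic checks and as the calibration target
#' of [asthma_scenario_config()]; the daily source data themselves are not
#' shareable.
#'
#' @return a list with `monthly_totals` (Jan..Dec), `dow_totals`
#'   (Mon..Sun), `total`, `zero_days`, `n_days`, `years`.
#' @export
published_admission_totals <- function() {
  list(
    monthly_totals = setNames(c(330L, 441L, 482L, 421L, 526L, 248L, 281L,
                                540L, 639L, 606L, 604L, 475L), month.abb),
    dow_totals = setNames(c(950L, 862L, 764L, 753L, 687L, 722L, 855L),
                          c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")),
    total = 5593L, zero_days = 616L, n_days = 2922L, years = 2016:2023)
}
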