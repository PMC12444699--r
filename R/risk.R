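#' Observed high-risk exceedance threshold
#'
#' The smallest integer count `t` such that the fraction of history days
#' with `count >= t` is at most `1 - percentile`. With the default 95th
#' percentile this is the "top 5% of days" rule on observed integer counts:
#' a day is high-risk when its admissions reach the threshold or more. The
#' integer "fraction >= t" rule (rather than an interpolated quantile) keeps
#' the "`t` or more admissions" reading exact, and the threshold is monotone
#' non-decreasing in `percentile`.
#'
#' @param history an `adm_series` (or integer vector) of historical counts.
#' @param percentile exceedance percentile in (0, 1); default 0.95.
#' @return integer threshold (>= 1).
#' @examples
#' observed_threshold(daily_series(as.Date("2020-01-01") + 0:9,
#'                                 c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)), 0.6)
#' @export
observed_threshold <- function(history, percentile = 0.95) {
  cnt <- if (inherits(history, "adm_series")) history$count else as.integer(history)
  if (length(cnt) == 0L) stop("empty history")
  if (percentile <= 0 || percentile >= 1) stop("`percentile` must be in (0, 1)")
  tail_frac <- 1 - percentile
  for (t in seq_len(max(cnt) + 1L)) {
    if (mean(cnt >= t) <= tail_frac) return(t)
  }
  max(cnt) + 1L
}

#' Prediction-side high-risk threshold
#'
#' Empirical percentile (linear-interpolation quantile, R type 7) of a set
#' of continuous model predictions; days with prediction strictly greater
#' than this threshold are flagged high-risk, so at most a fraction
#' `1 - percentile` (plus one day's worth) of days is ever flagged.
#'
#' @param predicted numeric vector of at least 20 predictions.
#' @param percentile percentile in (0, 1); default 0.95.
#' @return the numeric threshold.
#' @export
prediction_threshold <- function(predicted, percentile = 0.95) {
  predicted <- as.numeric(predicted)
  if (length(predicted) < 20L) stop("need at least 20 predicted values")
  if (percentile <= 0 || percentile >= 1) stop("`percentile` must be in (0, 1)")
  unname(quantile(predicted, probs = percentile, type = 7))
}

#' Classify days against a threshold
#'
#' Count-side classification of observed days uses the non-strict rule
#' (`count >= integer threshold`, "t or more admissions"); prediction-side
#' classification of continuous forecasts uses the strict rule
#' (`prediction > threshold`).
#'
#' @param values numeric vector.
#' @param threshold finite threshold.
#' @param strict flag values strictly greater than `threshold` (`TRUE`,
#'   prediction side) or greater-or-equal (`FALSE`, count side).
#' @return logical vector of flags.
#' @export
classify_days <- function(values, threshold, strict = TRUE) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  if (strict) values > threshold else values >= threshold
}

#' Calibrate the high-risk alert for a set of models
#'
#' Combines the observed integer exceedance threshold from historical counts
#' with per-model continuous thresholds computed from each model's
#' predictions (by default one-step-ahead predictions over the training
#' history, so no validation information enters the calibration).
#'
#' @param history an `adm_series` of historical counts.
#' @param predictions named list of numeric prediction vectors, one per
#'   model.
#' @param percentile percentile in (0, 1); default 0.95.
#' @return an object of class `risk_calibration`: `observed_threshold`,
#'   `prediction_thresholds` (named), `percentile`.
#' @export
risk_calibration <- function(history, predictions, percentile = 0.95) {
  obs <- observed_threshold(history, percentile)
  pred <- vapply(predictions, prediction_threshold, 0, percentile = percentile)
  structure(list(observed_threshold = obs, prediction_thresholds = pred,
                 percentile = percentile),
            class = "risk_calibration")
}

#' @export
print.risk_calibration <- function(x, ...) {
  cat(sprintf("<risk_calibration> %.0fth percentile\n", 100 * x$percentile))
  cat(sprintf("  observed threshold: %d or more admissions/day\n", x$observed_threshold))
  for (m in names(x$prediction_thresholds))
    cat(sprintf("  %-9s prediction threshold: %.2f\n", m, x$prediction_thresholds[[m]]))
  invisible(x)
}
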