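#' Difference a series
#'
#' Applies the first-difference operator `d` times; `difference(y, 1)` is
#' `y[t] - y[t-1]`. Differencing is the standard device for removing a
#' stochastic trend before ARMA modelling of a non-stationary series.
#'
#' @param x numeric vector.
#' @param d non-negative integer differencing order; `d = 0` returns `x`.
#' @return numeric vector of length `length(x) - d`.
#' @export
difference <- function(x, d = 1L) {
  d <- as.integer(d)
  if (d < 0L) stop("`d` must be >= 0")
  if (length(x) <= d) stop("series of length ", length(x),
                           " is too short to difference ", d, " time(s)")
  if (d == 0L) return(x)
  diff(x, differences = d)
}

## Published asymptotic critical values of the KPSS statistic.
kpss_critical <- list(
  level = c("0.10" = 0.347, "0.05" = 0.463, "0.025" = 0.574, "0.01" = 0.739),
  trend = c("0.10" = 0.119, "0.05" = 0.146, "0.025" = 0.176, "0.01" = 0.216))

#' KPSS stationarity test
#'
#' Tests the null hypothesis that a series is stationary around a constant
#' level (or, with `null = "trend"`, around a deterministic linear trend).
#' The statistic is `sum(S_t^2) / (n^2 * lrv)` where `S_t` are partial sums
#' of the regression residuals and `lrv` is the Bartlett-kernel long-run
#' variance estimate with `lags` autocovariance terms. Rejection (small
#' p-value) indicates non-stationarity.
#'
#' The p-value is interpolated linearly from the published critical-value
#' table; outside the table it is reported as an interval bound (`"p > 0.1"`
#' or `"p < 0.01"`) with the numeric `p_value` clamped to that bound.
#'
#' @param x numeric series, length >= 10.
#' @param lags Bartlett truncation lag, or `"auto"` for
#'   `floor(4 * (n/100)^0.25)`.
#' @param null `"level"` (default) or `"trend"` stationarity.
#' @return an `adm_test` list: `statistic`, `p_value`, `p_bound` (`NA` when
#'   the p-value is interior to the table), `lags_used`, `null_description`.
#' @export
kpss_test <- function(x, lags = "auto", null = c("level", "trend")) {
  null <- match.arg(null)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("KPSS requires at least 10 observations")
  if (identical(lags, "auto")) lags <- floor(4 * (n / 100)^0.25)
  lags <- as.integer(lags)
  e <- if (null == "level") x - mean(x) else residuals(lm(x ~ seq_len(n)))
  if (sum(e^2) == 0) stop("zero-variance series")
  s2 <- sum(e^2) / n
  if (lags > 0L) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  stat <- sum(cumsum(e)^2) / (n^2 * s2)
  cv <- kpss_critical[[null]]
  pv <- as.numeric(names(cv))
  if (stat < cv[1L]) {
    p <- 0.10; bound <- "p > 0.1"
  } else if (stat > cv[length(cv)]) {
    p <- 0.01; bound <- "p < 0.01"
  } else {
    p <- approx(cv, pv, xout = stat)$y
    bound <- NA_character_
  }
  structure(list(statistic = stat, p_value = p, p_bound = bound,
                 lags_used = lags,
                 null_description = paste0(null, " stationarity (KPSS)")),
            class = "adm_test")
}

#' @export
print.adm_test <- function(x, ...) {
  p <- if (!is.na(x$p_bound)) x$p_bound else sprintf("p = %.3f", x$p_value)
  cat(sprintf("%s: statistic %.4f, %s (lags %d)\n",
              x$null_description, x$statistic, p, x$lags_used))
  invisible(x)
}

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' `Q = n(n+2) * sum_{k=1..lags} r_k^2 / (n-k)` referred to a chi-square
#' distribution with `lags - fitdf` degrees of freedom; `fitdf` is the number
#' of ARMA coefficients estimated from the data. A small p-value indicates
#' the residuals are not white noise.
#'
#' @param residuals numeric residual series.
#' @param lags number of autocorrelations tested (default 10).
#' @param fitdf degrees of freedom consumed by the fitted model;
#'   `0 <= fitdf < lags`.
#' @return an `adm_test` list (`statistic`, `p_value`, `lags_used`,
#'   `fitdf`, `null_description`).
#' @export
ljung_box <- function(residuals, lags = 10L, fitdf = 0L) {
  lags <- as.integer(lags); fitdf <- as.integer(fitdf)
  if (fitdf < 0L) stop("`fitdf` must be >= 0")
  if (lags <= fitdf) stop("`lags` must exceed `fitdf` (zero degrees of freedom)")
  if (lags >= length(residuals)) stop("`lags` must be smaller than the series length")
  bt <- Box.test(residuals, lag = lags, type = "Ljung-Box", fitdf = fitdf)
  structure(list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
                 p_bound = NA_character_, lags_used = lags, fitdf = fitdf,
                 null_description = "residuals are white noise (Ljung-Box)"),
            class = "adm_test")
}

#' Sample autocorrelation / partial autocorrelation profile
#'
#' Returns the correlogram at lags `1..max_lag` together with the white-noise
#' 95% confidence band `qnorm(0.975)/sqrt(n)`. Lag 0 (identically 1 for the
#' ACF) is excluded. Partial autocorrelations are computed by the
#' Durbin-Levinson recursion, so `pacf_lags(x)$values[1]` equals
#' `acf_lags(x)$values[1]` exactly.
#'
#' @param x numeric series with positive variance.
#' @param max_lag largest lag, `max_lag < length(x)`.
#' @return an `adm_correlogram` list: `lags`, `values`, `conf_band`.
#' @export
acf_lags <- function(x, max_lag = 20L) {
  correlogram_checks(x, max_lag)
  v <- drop(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
  structure(list(lags = seq_len(max_lag), values = v,
                 conf_band = qnorm(0.975) / sqrt(length(x)), partial = FALSE),
            class = "adm_correlogram")
}

#' @rdname acf_lags
#' @export
pacf_lags <- function(x, max_lag = 20L) {
  correlogram_checks(x, max_lag)
  v <- drop(pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  structure(list(lags = seq_len(max_lag), values = v,
                 conf_band = qnorm(0.975) / sqrt(length(x)), partial = TRUE),
            class = "adm_correlogram")
}

correlogram_checks <- function(x, max_lag) {
  if (max_lag < 1L) stop("`max_lag` must be >= 1")
  if (max_lag >= length(x)) stop("`max_lag` must be smaller than the series length")
  if (var(as.numeric(x)) == 0) stop("constant series: autocorrelations undefined")
  invisible(TRUE)
}

#' @export
print.adm_correlogram <- function(x, ...) {
  cat(sprintf("<%s> lags 1..%d, white-noise band +-%.3f\n",
              if (x$partial) "PACF" else "ACF", max(x$lags), x$conf_band))
  print(round(setNames(x$values, x$lags), 3))
  invisible(x)
}

#' @importFrom stats approx
NULL
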