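#' Construct a forecast table
#'
#' Internal constructor for the `adm_forecast` class: a data frame with one
#' row per forecast date carrying the point estimate and 95% interval limits.
#' Enforces `lo95 <= point <= hi95`.
#'
#' @param date forecast dates (`Date`) or integer time indices.
#' @param point,lo95,hi95 numeric vectors of equal length.
#' @param model model name attached to every row.
#' @return an `adm_forecast` data frame.
#' @keywords internal
adm_forecast <- function(date, point, lo95, hi95, model) {
  stopifnot(length(point) == length(lo95), length(point) == length(hi95))
  if (any(lo95 > point + 1e-8) || any(hi95 < point - 1e-8))
    stop("interval limits must bracket the point forecast")
  structure(data.frame(date = date, point = point,
                       lo95 = pmin(lo95, point), hi95 = pmax(hi95, point),
                       model = model, stringsAsFactors = FALSE),
            class = c("adm_forecast", "data.frame"))
}

forecast_dates <- function(fit, h) {
  if (inherits(fit$last_date, "Date")) fit$last_date + seq_len(h)
  else fit$n + seq_len(h)
}

#' @export
print.adm_forecast <- function(x, ...) {
  cat(sprintf("<adm_forecast> %s, %d step(s)\n", x$model[1L], nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Combine member forecasts into an ensemble forecast
#'
#' The ensemble point forecast is the arithmetic mean of the member point
#' forecasts; the lower and upper 95% limits are likewise the means of the
#' member lower and upper limits (so the ensemble interval width is the mean
#' of the member widths). All members must cover the same dates.
#'
#' @param forecasts a list of two or more `adm_forecast` objects on
#'   identical dates.
#' @return an `adm_forecast` with `model = "ensemble"`.
#' @examples
#' f1 <- admitcast:::adm_forecast(1L, 2, 1, 5, "a")
#' f2 <- admitcast:::adm_forecast(1L, 4, 1, 7, "b")
#' ensemble_forecast(list(f1, f2))
#' @export
ensemble_forecast <- function(forecasts) {
  if (length(forecasts) < 2L) stop("ensemble needs at least 2 member forecasts")
  ref <- forecasts[[1L]]
  for (f in forecasts[-1L]) {
    if (nrow(f) != nrow(ref) || any(f$date != ref$date))
      stop("member forecasts cover different dates")
  }
  pts <- sapply(forecasts, `[[`, "point")
  los <- sapply(forecasts, `[[`, "lo95")
  his <- sapply(forecasts, `[[`, "hi95")
  if (is.null(dim(pts))) { pts <- rbind(pts); los <- rbind(los); his <- rbind(his) }
  adm_forecast(date = ref$date, point = rowMeans(pts),
               lo95 = rowMeans(los), hi95 = rowMeans(his), model = "ensemble")
}

## ---- shared adm_fit methods -------------------------------------------

#' @export
residuals.adm_fit <- function(object, ...) object$residuals

#' @export
logLik.adm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.adm_fit <- function(object, ...) {
  print(object)
  lb <- try(ljung_box(object$residuals, lags = 10L,
                      fitdf = min(object$fitdf %||% 0L, 9L)), silent = TRUE)
  if (!inherits(lb, "try-error")) print(lb)
  invisible(object)
}

#' @export
coef.ets_fit <- function(object, ...) {
  out <- c(alpha = object$alpha)
  if (object$spec$trend != "none") out <- c(out, beta = object$beta)
  if (object$spec$trend == "additive-damped") out <- c(out, phi = object$phi_damp)
  if (object$spec$seasonal == "additive") out <- c(out, gamma = object$gamma)
  out
}
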