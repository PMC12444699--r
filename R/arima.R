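#' Specify an ARIMA(p, d, q) model with optional constant
#'
#' `d = 0` models the series itself (the constant is its mean); `d = 1`
#' models the first-differenced series, with the constant acting as a drift
#' so long-range forecasts revert to the mean daily change of the series.
#'
#' @param p AR order (>= 0).
#' @param d differencing order, 0 or 1.
#' @param q MA order (>= 0).
#' @param include_constant include a constant (mean for `d = 0`, drift for
#'   `d = 1`).
#' @return an object of class `arima_spec`.
#' @export
arima_spec <- function(p = 0L, d = 1L, q = 2L, include_constant = TRUE) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (p < 0L || q < 0L) stop("`p` and `q` must be >= 0")
  if (!d %in% c(0L, 1L)) stop("`d` must be 0 or 1")
  if (p + q == 0L && !include_constant)
    stop("a model needs at least one ARMA term or a constant")
  structure(list(p = p, d = d, q = q, include_constant = isTRUE(include_constant)),
            class = "arima_spec")
}

arima_label <- function(spec) {
  sprintf("ARIMA(%d,%d,%d)%s", spec$p, spec$d, spec$q,
          if (spec$include_constant) "+c" else "")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat("<arima_spec>", arima_label(x), "\n"); invisible(x)
}

#' Fit an ARIMA model by exact Gaussian maximum likelihood
#'
#' Estimation is delegated to the state-space Kalman-filter maximum
#' likelihood in [stats::arima()] (`method = "ML"`), which keeps AR roots
#' stationary and MA roots invertible through its transformed
#' parameterisation. For `d = 1` with a constant, the constant is fitted as
#' a drift via a linear time regressor, since the plain differenced model
#' has no mean term.
#'
#' @param series an `adm_series` or numeric vector.
#' @param spec an [arima_spec()].
#' @param init optional initial coefficient vector (warm start for daily
#'   refits).
#' @return an object of class `c("arima_fit", "adm_fit")` with elements
#'   `phi`, `theta`, `constant` (mean for `d = 0`, drift/day for `d = 1`),
#'   `sigma2`, `loglik`, `aic`, `bic`, `residuals`, `fit` (the underlying
#'   `Arima` object), `converged`.
#' @export
fit_arima <- function(series, spec = arima_spec(), init = NULL) {
  y <- if (inherits(series, "adm_series")) as.numeric(series$count) else as.numeric(series)
  n <- length(y)
  if (n < 10L * (spec$p + spec$q + 1L))
    stop("series too short for ", arima_label(spec),
         " (need >= ", 10L * (spec$p + spec$q + 1L), " points)")
  if (var(y) == 0) {
    ## a constant window (e.g. an all-zero pandemic stretch) admits no ARMA
    ## estimation; return the deterministic fit that forecasts the constant
    return(structure(list(spec = spec, phi = numeric(0), theta = numeric(0),
                          constant = y[1L], sigma2 = 0, loglik = NA_real_,
                          aic = NA_real_, bic = NA_real_, k = 1L, fitdf = 0L,
                          residuals = rep(0, n), fit = NULL, n = n,
                          converged = TRUE, degenerate = TRUE,
                          last_date = if (inherits(series, "adm_series"))
                            series$date[n] else NA,
                          model_name = "arima"),
                     class = c("arima_fit", "adm_fit")))
  }

  drift <- spec$d == 1L && spec$include_constant
  xreg <- if (drift) matrix(seq_len(n), dimnames = list(NULL, "drift"))
  fit <- NULL
  for (method in c("ML", "CSS-ML")) {
    fit <- try(suppressWarnings(arima(
      y, order = c(spec$p, spec$d, spec$q), xreg = xreg,
      include.mean = spec$d == 0L && spec$include_constant,
      method = method, optim.control = list(maxit = 500L),
      init = init)), silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (!inherits(fit, "try-error"))
    fit$call$xreg <- xreg  # predict() re-evaluates the call's xreg
  if (inherits(fit, "try-error"))
    stop("ARIMA estimation failed to converge for ", arima_label(spec))
  converged <- is.null(fit$code) || fit$code == 0L
  if (!converged) warning("optimizer reported non-convergence for ", arima_label(spec))

  cf <- coef(fit)
  phi <- unname(cf[grep("^ar", names(cf))])
  theta <- unname(cf[grep("^ma", names(cf))])
  constant <- if (drift) unname(cf["drift"])
              else if (spec$d == 0L && spec$include_constant) unname(cf["intercept"])
              else 0
  k <- length(cf) + 1L
  structure(list(spec = spec, phi = phi, theta = theta, constant = constant,
                 sigma2 = fit$sigma2, loglik = fit$loglik,
                 aic = fit$aic, bic = BIC(fit), k = k,
                 fitdf = spec$p + spec$q,
                 residuals = as.numeric(residuals(fit)),
                 fit = fit, n = n, converged = converged,
                 last_date = if (inherits(series, "adm_series")) series$date[n] else NA,
                 model_name = "arima"),
            class = c("arima_fit", "adm_fit"))
}

#' @export
coef.arima_fit <- function(object, ...) coef(object$fit)

#' @export
print.arima_fit <- function(x, ...) {
  cat(sprintf("%s fit, n = %d\n", arima_label(x$spec), x$n))
  if (length(x$phi)) cat("  phi:  ", paste(sprintf("%.4f", x$phi), collapse = " "), "\n")
  if (length(x$theta)) cat("  theta:", paste(sprintf("%.4f", x$theta), collapse = " "), "\n")
  if (x$spec$include_constant)
    cat(sprintf("  constant: %.4f (%s)\n", x$constant,
                if (x$spec$d == 1L) "drift/day" else "mean"))
  cat(sprintf("  sigma2 %.4f  logLik %.2f  AIC %.1f  BIC %.1f\n",
              x$sigma2, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Select an ARIMA specification by BIC with a white-noise residual gate
#'
#' Fits every candidate, screens them with the Ljung-Box test on residuals
#' (10 lags, `fitdf = p + q`), and returns the BIC-minimal candidate whose
#' residual p-value exceeds `lb_alpha`. If no candidate passes the residual
#' gate, the overall BIC-minimal candidate is returned with a warning. Ties
#' are broken by fewer parameters, then lexicographically by `(p, q)`.
#'
#' @param series an `adm_series` or numeric vector.
#' @param candidates list of [arima_spec()] objects.
#' @param lb_alpha residual white-noise p-value gate (default 0.05).
#' @param lb_lags Ljung-Box lags (default 10).
#' @return the winning `arima_spec`, with attributes `selection_table`
#'   (data frame of BIC and residual p-values) and `fit`.
#' @export
select_arima <- function(series, candidates = list(
                           arima_spec(0, 1, 1), arima_spec(0, 1, 2),
                           arima_spec(0, 1, 3), arima_spec(1, 1, 1),
                           arima_spec(2, 1, 0)),
                         lb_alpha = 0.05, lb_lags = 10L) {
  if (length(candidates) == 0L) stop("empty candidate list")
  fits <- lapply(candidates, function(sp) try(fit_arima(series, sp), silent = TRUE))
  ok <- !vapply(fits, inherits, TRUE, what = "try-error")
  if (!any(ok)) stop("all ARIMA candidates failed to converge")
  candidates <- candidates[ok]; fits <- fits[ok]
  bic <- vapply(fits, `[[`, 0, "bic")
  lb_p <- vapply(fits, function(f)
    ljung_box(f$residuals, lags = lb_lags, fitdf = min(f$fitdf, lb_lags - 1L))$p_value, 0)
  npar <- vapply(candidates, function(s) s$p + s$q + s$include_constant, 0)
  tab <- data.frame(model = vapply(candidates, arima_label, ""),
                    bic = bic, lb_p = lb_p, npar = npar)
  pass <- lb_p > lb_alpha
  pool <- if (any(pass)) which(pass) else seq_along(candidates)
  if (!any(pass))
    warning("no candidate passed the residual white-noise check; ",
            "returning the BIC-minimal model")
  ord <- order(bic[pool], npar[pool],
               vapply(candidates[pool], `[[`, 0L, "p"),
               vapply(candidates[pool], `[[`, 0L, "q"))
  win <- pool[ord[1L]]
  spec <- candidates[[win]]
  attr(spec, "selection_table") <- tab
  attr(spec, "fit") <- fits[[win]]
  spec
}

#' @export
forecast.arima_fit <- function(object, h = 1L, ...) {
  h <- as.integer(h)
  if (h < 1L) stop("`h` must be >= 1")
  if (isTRUE(object$degenerate)) {
    pt <- rep(object$constant, h)
    return(adm_forecast(date = forecast_dates(object, h), point = pt,
                        lo95 = pt, hi95 = pt, model = "arima"))
  }
  drift <- object$spec$d == 1L && object$spec$include_constant
  pr <- predict(object$fit, n.ahead = h,
                newxreg = if (drift)
                  matrix(object$n + seq_len(h), dimnames = list(NULL, "drift")))
  point <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  z <- qnorm(0.975)
  adm_forecast(date = forecast_dates(object, h), point = point,
               lo95 = point - z * se, hi95 = point + z * se, model = "arima")
}
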