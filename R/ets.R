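#' Specify an additive innovations state-space (ETS) model
#'
#' The additive ETS class covers simple exponential smoothing
#' (`trend = "none"`), Holt's linear trend (`"additive"`), the damped-trend
#' variant (`"additive-damped"`), and additive seasonality with period
#' `period`. Errors are additive in all variants; multiplicative forms are
#' out of scope for low-count admission data where they are numerically
#' fragile.
#'
#' @param trend `"none"`, `"additive"`, or `"additive-damped"`.
#' @param seasonal `"none"` or `"additive"`.
#' @param period seasonal period `m` (days); ignored when
#'   `seasonal = "none"`. The default 7 is the weekly cycle.
#' @return an object of class `ets_spec`.
#' @export
ets_spec <- function(trend = c("none", "additive", "additive-damped"),
                     seasonal = c("none", "additive"), period = 7L) {
  trend <- match.arg(trend)
  seasonal <- match.arg(seasonal)
  period <- as.integer(period)
  if (seasonal == "additive" && period < 2L)
    stop("seasonal models need `period` >= 2")
  structure(list(error = "additive", trend = trend, seasonal = seasonal,
                 period = if (seasonal == "additive") period else 1L),
            class = "ets_spec")
}

#' @export
print.ets_spec <- function(x, ...) {
  cat(sprintf("<ets_spec> ETS(A,%s,%s)%s\n",
              switch(x$trend, none = "N", additive = "A", `additive-damped` = "Ad"),
              if (x$seasonal == "additive") "A" else "N",
              if (x$seasonal == "additive") sprintf(" period %d", x$period) else ""))
  invisible(x)
}

ets_label <- function(spec) {
  sprintf("ETS(A,%s,%s)",
          switch(spec$trend, none = "N", additive = "A", `additive-damped` = "Ad"),
          if (spec$seasonal == "additive") "A" else "N")
}

## Internal parameter layout (all optimized jointly):
##   alpha, [beta_frac], [phi], [gamma_frac], l0, [b0], [s0_1..s0_{m-1}]
## beta = alpha * beta_frac and gamma = (1 - alpha) * gamma_frac keep the
## usual additive-class admissibility constraints (0 < beta < alpha,
## 0 < gamma < 1 - alpha) as plain box constraints. The m-th initial
## seasonal is minus the sum of the others (seasonals sum to zero).
ets_par_pack <- function(spec, alpha, beta, gamma, phi, l0, b0, s0) {
  p <- alpha
  if (spec$trend != "none") p <- c(p, beta / alpha)
  if (spec$trend == "additive-damped") p <- c(p, phi)
  if (spec$seasonal == "additive") p <- c(p, gamma / (1 - alpha))
  p <- c(p, l0)
  if (spec$trend != "none") p <- c(p, b0)
  if (spec$seasonal == "additive") p <- c(p, s0[seq_len(spec$period - 1L)])
  p
}

ets_par_unpack <- function(spec, par) {
  i <- 1L
  alpha <- par[i]; i <- i + 1L
  beta <- 0; phi <- 1; gamma <- 0
  if (spec$trend != "none") { beta <- alpha * par[i]; i <- i + 1L }
  if (spec$trend == "additive-damped") { phi <- par[i]; i <- i + 1L }
  if (spec$seasonal == "additive") { gamma <- (1 - alpha) * par[i]; i <- i + 1L }
  l0 <- par[i]; i <- i + 1L
  b0 <- 0
  if (spec$trend != "none") { b0 <- par[i]; i <- i + 1L }
  s0 <- numeric(0)
  if (spec$seasonal == "additive") {
    s_free <- par[seq.int(i, length.out = spec$period - 1L)]
    s0 <- c(s_free, -sum(s_free))
  }
  list(alpha = alpha, beta = beta, gamma = gamma, phi = phi,
       l0 = l0, b0 = b0, s0 = s0)
}

ets_bounds <- function(spec, y) {
  span <- max(abs(y)) + 10 * (sd(y) + 1)
  lo <- 1e-4; hi <- 0.9999
  lower <- lo; upper <- hi                       # alpha
  if (spec$trend != "none") { lower <- c(lower, 1e-4); upper <- c(upper, hi) }
  if (spec$trend == "additive-damped") { lower <- c(lower, 0.8); upper <- c(upper, 0.98) }
  if (spec$seasonal == "additive") { lower <- c(lower, 1e-4); upper <- c(upper, hi) }
  lower <- c(lower, -span); upper <- c(upper, span)          # l0
  if (spec$trend != "none") { lower <- c(lower, -span); upper <- c(upper, span) }
  if (spec$seasonal == "additive") {
    lower <- c(lower, rep(-span, spec$period - 1L))
    upper <- c(upper, rep(span, spec$period - 1L))
  }
  list(lower = lower, upper = upper)
}

ets_run_filter <- function(spec, y, pars) {
  ets_filter_cpp(y, pars$alpha, pars$beta, pars$gamma, pars$phi,
                 pars$l0, pars$b0,
                 if (spec$seasonal == "additive") pars$s0 else numeric(0),
                 spec$trend != "none", spec$seasonal == "additive")
}

ets_heuristic_start <- function(spec, y) {
  m <- spec$period
  n <- length(y)
  s0 <- numeric(0)
  if (spec$seasonal == "additive") {
    k <- n %/% m
    mat <- matrix(y[seq_len(k * m)], nrow = m)
    s0 <- rowMeans(mat) - mean(mat)
    l0 <- mean(mat)
  } else {
    l0 <- mean(y[seq_len(min(n, 10L))])
  }
  b0 <- 0
  if (spec$trend != "none") {
    k <- min(n, max(2L * m, 10L))
    b0 <- unname(coef(lm(y[seq_len(k)] ~ seq_len(k)))[2L])
    l0 <- l0 - b0 * min(n, 10L) / 2
  }
  list(alpha = 0.2, beta = 0.05, gamma = 0.05, phi = 0.95,
       l0 = l0, b0 = b0, s0 = s0)
}

#' Fit an additive ETS model by Gaussian maximum likelihood
#'
#' Runs the additive innovations state-space recursions (one-step error
#' `e_t = y_t - (l + phi*b + s_{t-m})`, states updated by the standard
#' additive equations) and maximizes the Gaussian likelihood over the
#' smoothing parameters *and* the initial states jointly, using bounded
#' quasi-Newton (`L-BFGS-B`) from a heuristic start plus two fixed
#' alternative starts. `-2 logLik = n * (log(2*pi*SSE/n) + 1)`; the AIC
#' counts smoothing parameters, free initial states and the innovation
#' variance.
#'
#' @param series an `adm_series` or numeric vector.
#' @param spec an [ets_spec()].
#' @param start optional warm start: the `par` element of a previous fit on
#'   a similar window (skips the heuristic restarts; used by the daily-refit
#'   backtest).
#' @param hessian compute the observed-information standard errors of the
#'   smoothing parameters (natural scale, delta method not required).
#' @return an object of class `c("ets_fit", "adm_fit")` with elements
#'   `alpha`, `beta`, `gamma`, `phi_damp`, `initial_level`, `initial_trend`,
#'   `initial_seasonals`, `sigma2`, `loglik`, `aic`, `residuals`, `fitted`,
#'   `states` (end-of-sample level/trend/seasonal buffer), `converged`.
#' @export
fit_ets <- function(series, spec = ets_spec(), start = NULL, hessian = FALSE) {
  y <- if (inherits(series, "adm_series")) as.numeric(series$count) else as.numeric(series)
  n <- length(y)
  m <- spec$period
  if (spec$seasonal == "additive" && n < 3L * m)
    stop("seasonal ETS needs at least 3 full periods (", 3L * m, " points)")
  if (n < 5L) stop("series too short for ETS estimation")
  if (var(y) == 0) {
    ## constant window: the innovation variance is zero; forecast the constant
    return(structure(list(spec = spec, alpha = 0.5, beta = 0, gamma = 0,
                          phi_damp = 1, initial_level = y[1L],
                          initial_trend = 0,
                          initial_seasonals = rep(0, spec$period),
                          sigma2 = 0, loglik = NA_real_, aic = NA_real_,
                          k = 3L, residuals = rep(0, n), fitted = y,
                          states = list(level = y[1L], trend = 0,
                                        seasonal = rep(0, spec$period), n = n),
                          par = NULL, se = NULL, n = n, converged = TRUE,
                          degenerate = TRUE,
                          last_date = if (inherits(series, "adm_series"))
                            series$date[n] else NA,
                          model_name = "ets"),
                     class = c("ets_fit", "adm_fit")))
  }

  b <- ets_bounds(spec, y)
  obj <- function(par) {
    pars <- ets_par_unpack(spec, par)
    fl <- ets_run_filter(spec, y, pars)
    n * log(fl$sse / n)
  }

  starts <- if (!is.null(start)) {
    list(pmin(pmax(start, b$lower), b$upper))
  } else {
    h <- ets_heuristic_start(spec, y)
    base <- ets_par_pack(spec, h$alpha, h$beta, h$gamma, h$phi, h$l0, h$b0, h$s0)
    alt1 <- ets_par_pack(spec, 0.5, 0.1, 0.1, 0.9, h$l0, h$b0, h$s0)
    alt2 <- ets_par_pack(spec, 0.05, 0.01, 0.2, 0.97, h$l0, h$b0, h$s0)
    lapply(list(base, alt1, alt2), function(p) pmin(pmax(p, b$lower), b$upper))
  }

  best <- NULL
  converged <- FALSE
  for (p0 in starts) {
    o <- try(optim(p0, obj, method = "L-BFGS-B", lower = b$lower,
                   upper = b$upper, control = list(maxit = 500L)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) {
      best <- o
      ## 52 = line-search saturation, typical when started at the optimum
      converged <- o$convergence %in% c(0L, 52L)
    }
  }
  if (is.null(best)) stop("ETS optimisation failed to produce any fit")
  if (!converged)
    warning("ETS optimiser did not report convergence for ", ets_label(spec))

  pars <- ets_par_unpack(spec, best$par)
  fl <- ets_run_filter(spec, y, pars)
  sigma2 <- fl$sse / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- 1L + (spec$trend != "none") + (spec$trend == "additive-damped") +
    (spec$seasonal == "additive") +                      # smoothing parameters
    1L + (spec$trend != "none") +
    (if (spec$seasonal == "additive") m - 1L else 0L) +  # free initial states
    1L                                                   # sigma2
  se <- NULL
  if (hessian) {
    ## observed information in the natural (alpha, beta, gamma, phi) scale
    nat <- c(alpha = pars$alpha,
             if (spec$trend != "none") c(beta = pars$beta),
             if (spec$trend == "additive-damped") c(phi = pars$phi),
             if (spec$seasonal == "additive") c(gamma = pars$gamma))
    nsm <- length(nat)
    obj_nat <- function(v) {
      pp <- pars
      pp$alpha <- v[1L]; i <- 2L
      if (spec$trend != "none") { pp$beta <- v[i]; i <- i + 1L }
      if (spec$trend == "additive-damped") { pp$phi <- v[i]; i <- i + 1L }
      if (spec$seasonal == "additive") pp$gamma <- v[i]
      fl2 <- ets_run_filter(spec, y, pp)
      n / 2 * log(fl2$sse / n)
    }
    H <- optimHess(nat, obj_nat)
    se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, nsm))
    names(se) <- names(nat)
  }
  structure(list(spec = spec, alpha = pars$alpha, beta = pars$beta,
                 gamma = pars$gamma, phi_damp = pars$phi,
                 initial_level = pars$l0, initial_trend = pars$b0,
                 initial_seasonals = pars$s0, sigma2 = sigma2,
                 loglik = loglik, aic = -2 * loglik + 2 * k, k = k,
                 residuals = fl$residuals, fitted = fl$fitted,
                 states = list(level = fl$level, trend = fl$trend,
                               seasonal = fl$seasonal, n = fl$n),
                 par = best$par, se = se, n = n, converged = converged,
                 last_date = if (inherits(series, "adm_series")) series$date[n] else NA,
                 model_name = "ets"),
            class = c("ets_fit", "adm_fit"))
}

#' Select an additive ETS specification by AIC
#'
#' Fits each candidate specification and returns the one with the smallest
#' AIC. The default candidate set is simple exponential smoothing, Holt's
#' linear trend, the damped-trend variant, and weekly additive seasonality.
#'
#' @param series an `adm_series` or numeric vector.
#' @param candidates list of [ets_spec()] objects.
#' @return the winning `ets_spec`, with attributes `aic_table` (named AIC
#'   vector) and `fit` (the winning fit).
#' @export
select_ets <- function(series, candidates = list(
                         ets_spec("none", "none"),
                         ets_spec("additive", "none"),
                         ets_spec("additive-damped", "none"),
                         ets_spec("none", "additive", period = 7L))) {
  if (length(candidates) == 0L) stop("empty candidate list")
  fits <- lapply(candidates, function(sp)
    try(fit_ets(series, sp), silent = TRUE))
  ok <- !vapply(fits, inherits, TRUE, what = "try-error")
  if (!any(ok)) stop("all ETS candidates failed to fit")
  aics <- vapply(fits[ok], `[[`, 0, "aic")
  names(aics) <- vapply(candidates[ok], ets_label, "")
  win <- which.min(aics)
  spec <- candidates[ok][[win]]
  attr(spec, "aic_table") <- aics
  attr(spec, "fit") <- fits[ok][[win]]
  spec
}

## h-step variance multipliers c_j of the additive class:
##   c_j = alpha + beta * (phi + ... + phi^j) + gamma * 1{j = 0 mod m}
ets_cj <- function(fit, j) {
  spec <- fit$spec
  phi_cum <- if (spec$trend == "none") 0 * j else {
    if (spec$trend == "additive") j else fit$phi_damp * (1 - fit$phi_damp^j) / (1 - fit$phi_damp)
  }
  fit$alpha + fit$beta * phi_cum +
    (if (spec$seasonal == "additive") fit$gamma * (j %% spec$period == 0L) else 0)
}

#' @export
forecast.ets_fit <- function(object, h = 1L, ...) {
  h <- as.integer(h)
  if (h < 1L) stop("`h` must be >= 1")
  spec <- object$spec
  l <- object$states$level; b <- object$states$trend
  s <- object$states$seasonal; n <- object$states$n
  point <- numeric(h)
  for (i in seq_len(h)) {
    phi_cum <- if (spec$trend == "none") 0 else {
      if (spec$trend == "additive") i
      else object$phi_damp * (1 - object$phi_damp^i) / (1 - object$phi_damp)
    }
    seas <- if (spec$seasonal == "additive") s[((n + i - 1L) %% spec$period) + 1L] else 0
    point[i] <- l + phi_cum * b + seas
  }
  v <- numeric(h)
  cj2 <- if (h > 1L) cumsum(ets_cj(object, seq_len(h - 1L))^2) else numeric(0)
  v[1L] <- object$sigma2
  if (h > 1L) v[-1L] <- object$sigma2 * (1 + cj2)
  z <- qnorm(0.975)
  adm_forecast(date = forecast_dates(object, h), point = point,
               lo95 = point - z * sqrt(v), hi95 = point + z * sqrt(v),
               model = "ets")
}

#' Simulate a series from an additive ETS process
#'
#' Generates data from the same recursions used in fitting, with iid Gaussian
#' innovations; used for parameter-recovery and coverage checks.
#'
#' @param spec an [ets_spec()].
#' @param n series length.
#' @param params list with `alpha`, `beta`, `gamma`, `phi`, `l0`, `b0`, `s0`
#'   (length `period`), `sigma`.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_ets <- function(spec, n, params, seed = 1L) {
  set.seed(seed)
  e <- rnorm(n, 0, params$sigma)
  ets_simulate_cpp(e, params$alpha, params$beta %||% 0, params$gamma %||% 0,
                   params$phi %||% 1, params$l0, params$b0 %||% 0,
                   params$s0 %||% numeric(0),
                   spec$trend != "none", spec$seasonal == "additive")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ets_fit <- function(x, ...) {
  cat(sprintf("%s fit, n = %d\n", ets_label(x$spec), x$n))
  cat(sprintf("  alpha %.4f", x$alpha))
  if (x$spec$trend != "none") cat(sprintf("  beta %.4f", x$beta))
  if (x$spec$trend == "additive-damped") cat(sprintf("  phi %.3f", x$phi_damp))
  if (x$spec$seasonal == "additive") cat(sprintf("  gamma %.4f", x$gamma))
  cat(sprintf("\n  sigma2 %.4f  logLik %.2f  AIC %.1f\n", x$sigma2, x$loglik, x$aic))
  invisible(x)
}
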