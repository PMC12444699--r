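#' Specify a piecewise-linear-trend model with Fourier seasonality
#'
#' A decomposable forecaster `y(t) = g(t) + s(t) + e_t` in the style of
#' generalized-additive trend models: `g(t)` is a piecewise-linear trend
#' whose slope changes by `delta_j` at each of `S` changepoints spread evenly
#' over the first 80% of the history, with a Laplace(0, tau) prior on the
#' `delta_j` (so the MAP estimate is least squares with an L1 penalty
#' `lambda = 1/tau` on the slope changes); `s(t)` is a sum of weekly
#' (period 7) and yearly (period 365.25) Fourier terms with unpenalized
#' coefficients; the holiday term is fixed at zero. Larger `tau` means a
#' more flexible trend.
#'
#' @param n_changepoints number of potential trend changepoints `S` (>= 0).
#' @param changepoint_scale Laplace scale `tau` (> 0) of the slope-change
#'   prior, on the scale of the max-normalized series per unit of scaled
#'   time.
#' @param weekly_order,yearly_order Fourier orders (>= 0; 0 disables that
#'   seasonal block).
#' @param uncertainty_samples Monte-Carlo draws used for forecast intervals.
#' @param seed default RNG seed for interval simulation.
#' @return an object of class `prophet_spec`.
#' @export
prophet_spec <- function(n_changepoints = 25L, changepoint_scale = 0.05,
                         weekly_order = 3L, yearly_order = 10L,
                         uncertainty_samples = 300L, seed = 1L) {
  if (n_changepoints < 0L) stop("`n_changepoints` must be >= 0")
  if (!is.finite(changepoint_scale) && !is.infinite(changepoint_scale))
    stop("`changepoint_scale` must be positive (Inf = no penalty)")
  if (changepoint_scale <= 0) stop("`changepoint_scale` must be > 0")
  if (weekly_order < 0L || yearly_order < 0L) stop("Fourier orders must be >= 0")
  structure(list(n_changepoints = as.integer(n_changepoints),
                 changepoint_scale = changepoint_scale,
                 weekly_order = as.integer(weekly_order),
                 yearly_order = as.integer(yearly_order),
                 interval_level = 0.95,
                 uncertainty_samples = as.integer(uncertainty_samples),
                 seed = as.integer(seed)),
            class = "prophet_spec")
}

#' @export
print.prophet_spec <- function(x, ...) {
  cat(sprintf("<prophet_spec> S = %d changepoints, tau = %g, weekly order %d, yearly order %d\n",
              x$n_changepoints, x$changepoint_scale, x$weekly_order, x$yearly_order))
  invisible(x)
}

## design matrices depend only on (n, S, orders) for a 0-based day index,
## so daily sliding-window refits can reuse one cached copy
.design_cache <- new.env(parent = emptyenv())

prophet_design <- function(t_days, T_scale, cp_ts, weekly_order, yearly_order) {
  ts <- t_days / T_scale
  X <- cbind(trend = ts, offset = rep(1, length(ts)))
  if (length(cp_ts)) {
    H <- matrix(vapply(cp_ts, function(s) pmax(ts - s, 0), numeric(length(ts))),
                nrow = length(ts),
                dimnames = list(NULL, paste0("delta", seq_along(cp_ts))))
    X <- cbind(X, H)
  }
  for (k in seq_len(weekly_order))
    X <- cbind(X, setNames(data.frame(sin(2 * pi * k * t_days / 7),
                                      cos(2 * pi * k * t_days / 7)),
                           paste0(c("wsin", "wcos"), k)))
  for (k in seq_len(yearly_order))
    X <- cbind(X, setNames(data.frame(sin(2 * pi * k * t_days / 365.25),
                                      cos(2 * pi * k * t_days / 365.25)),
                           paste0(c("ysin", "ycos"), k)))
  as.matrix(X)
}

## Minimise 1/2 ||y - X b||^2 + lambda * sum_{j in pen} |b_j|.
## The unpenalized block (trend, offset, Fourier terms) is profiled out
## exactly by QR; cyclic coordinate descent then runs only on the small
## residualized changepoint block, followed by an exact linear-system
## polish on its active set. Deterministic.
lasso_cd <- function(X, y, lambda, pen, beta0 = NULL,
                     max_sweeps = 1000L, tol = 1e-9) {
  p <- ncol(X)
  y <- as.numeric(y)
  beta <- numeric(p)
  ols <- function(A, b) {
    cf <- qr.coef(qr(A), b)
    cf[is.na(cf)] <- 0  # aliased columns contribute nothing
    cf
  }
  if (!any(pen) || lambda == 0) return(unname(ols(X, y)))

  U <- X[, !pen, drop = FALSE]
  P <- X[, pen, drop = FALSE]
  qrU <- qr(U)
  yt <- qr.resid(qrU, y)
  Pt <- qr.resid(qrU, P)
  bP <- if (is.null(beta0)) numeric(ncol(P)) else as.numeric(beta0[pen])
  ## short CD rounds identify the active set; the exact KKT solve on that
  ## set finishes the optimisation (CD alone crawls on the near-collinear
  ## hinge columns); the KKT residual decides convergence
  for (round in 1:5) {
    bP <- lasso_cd_cpp(Pt, yt, lambda, rep(TRUE, ncol(P)), bP, 200L, tol)
    active <- abs(bP) > 0
    if (any(active)) {
      PA <- Pt[, active, drop = FALSE]
      sA <- sign(bP[active])
      sol <- try(solve(crossprod(PA), crossprod(PA, yt) - lambda * sA),
                 silent = TRUE)
      if (!inherits(sol, "try-error") &&
          all(sign(sol) == sA | sol == 0)) bP[active] <- sol
    }
    grad <- as.numeric(crossprod(Pt, yt - Pt %*% bP))
    ok_inactive <- all(abs(grad[!active]) <= lambda * (1 + 1e-8))
    ok_active <- !any(active) ||
      all(abs(grad[active] - lambda * sign(bP[active])) <=
            1e-6 * max(1, lambda))
    if (ok_inactive && ok_active) break
  }
  beta[pen] <- bP
  beta[!pen] <- ols(U, y - P %*% bP)
  unname(beta)
}

#' Fit the piecewise-linear-trend model
#'
#' MAP estimation of the model in [prophet_spec()]: the series is scaled by
#' its maximum absolute value, time by the training span, and the scaled
#' model is fit by L1-penalized least squares (penalty `1/tau` on the
#' changepoint slope adjustments only) using coordinate descent with an
#' exact active-set polish. Coefficients are reported per day on the
#' original count scale.
#'
#' @param series an `adm_series` or numeric vector.
#' @param spec a [prophet_spec()].
#' @param warm optional scaled coefficient vector from a previous fit on a
#'   similar window (daily-refit warm start).
#' @return an object of class `c("prophet_fit", "adm_fit")`: `base_rate`
#'   (`k`, slope/day at t = 0), `offset` (`m`, level at the first training
#'   day), `deltas` (slope changes/day at the changepoints),
#'   `changepoint_dates`, `fourier_coefs`, `sigma2`, `residuals`, `fitted`.
#' @export
fit_prophet <- function(series, spec = prophet_spec(), warm = NULL) {
  y <- if (inherits(series, "adm_series")) as.numeric(series$count) else as.numeric(series)
  n <- length(y)
  if (spec$yearly_order > 0L && n < 2L * 366L)
    stop("yearly seasonality needs at least two full years of history")
  if (n < 10L) stop("series too short")

  t_days <- seq_len(n) - 1
  T_scale <- max(n - 1, 1)
  S <- spec$n_changepoints
  key <- paste(n, S, spec$weekly_order, spec$yearly_order, sep = "|")
  cached <- get0(key, envir = .design_cache)
  if (is.null(cached)) {
    cp_idx <- integer(0)
    if (S > 0L) {
      hist_cut <- floor(0.8 * n)
      cp_idx <- unique(pmax(2L, round(seq(2L, hist_cut, length.out = S))))
    }
    cp_ts <- t_days[cp_idx] / T_scale
    cached <- list(X = prophet_design(t_days, T_scale, cp_ts,
                                      spec$weekly_order, spec$yearly_order),
                   cp_idx = cp_idx, cp_ts = cp_ts)
    assign(key, cached, envir = .design_cache)
  }
  X <- cached$X
  cp_idx <- cached$cp_idx
  cp_ts <- cached$cp_ts
  y_scale <- max(abs(y), 1e-12)
  ys <- y / y_scale
  pen <- grepl("^delta", colnames(X))
  beta <- if (!is.null(warm) && length(warm) == ncol(X)) warm
  if (is.infinite(spec$changepoint_scale)) {
    beta <- lasso_cd(X, ys, 0, pen, beta0 = beta)
  } else {
    ## MAP for Gaussian noise with a Laplace(0, tau) prior on the slope
    ## changes: L1 penalty lambda = sigma^2 / tau on the scaled series,
    ## with sigma^2 estimated alongside by a short fixed-point iteration
    ## (an over- or under-stated noise level would mis-weight the prior)
    sig2 <- if (!is.null(beta)) {
      mean((ys - X %*% beta)^2)         # warm refit: previous day's fit
    } else {
      Xu <- X[, !pen, drop = FALSE]     # changepoint-free least squares
      mean(qr.resid(qr(Xu), ys)^2)
    }
    for (it in 1:2) {
      lambda <- sig2 / spec$changepoint_scale
      beta <- lasso_cd(X, ys, lambda, pen, beta0 = beta)
      sig2 <- mean((ys - X %*% beta)^2)
    }
  }
  fitted_s <- as.numeric(X %*% beta)
  resid <- y - fitted_s * y_scale
  df <- sum(!pen | abs(beta) > 0)
  sigma2 <- sum(resid^2) / max(n - df, 1L)

  fourier <- beta[!pen & !colnames(X) %in% c("trend", "offset")] * y_scale
  names(fourier) <- colnames(X)[!pen & !colnames(X) %in% c("trend", "offset")]
  dates <- if (inherits(series, "adm_series")) series$date else NULL
  structure(list(spec = spec,
                 base_rate = beta[1L] * y_scale / T_scale,
                 offset = beta[2L] * y_scale,
                 deltas = beta[pen] * y_scale / T_scale,
                 changepoint_idx = cp_idx,
                 changepoint_dates = if (!is.null(dates)) dates[cp_idx] else cp_idx,
                 fourier_coefs = fourier, sigma2 = sigma2,
                 residuals = resid, fitted = fitted_s * y_scale,
                 beta_scaled = beta, cp_ts = cp_ts, y_scale = y_scale,
                 T_scale = T_scale, n = n, k = df + 1L,
                 loglik = -n / 2 * (log(2 * pi * sum(resid^2) / n) + 1),
                 last_date = if (!is.null(dates)) dates[n] else NA,
                 model_name = "prophet"),
            class = c("prophet_fit", "adm_fit"))
}

#' @export
coef.prophet_fit <- function(object, ...) {
  c(base_rate = object$base_rate, offset = object$offset, object$fourier_coefs)
}

#' @export
print.prophet_fit <- function(x, ...) {
  cat(sprintf("piecewise-trend fit, n = %d\n", x$n))
  cat(sprintf("  base slope %.5f/day, offset %.3f, %d/%d active changepoints\n",
              x$base_rate, x$offset, sum(abs(x$deltas) > 0), length(x$deltas)))
  cat(sprintf("  weekly order %d, yearly order %d, sigma2 %.4f\n",
              x$spec$weekly_order, x$spec$yearly_order, x$sigma2))
  invisible(x)
}

#' @export
#' @rdname fit_prophet
#' @param object a `prophet_fit`.
#' @param h forecast horizon in days.
#' @param seed RNG seed for the interval simulation (default: the spec
#'   seed, so repeated calls reproduce identical intervals).
#' @param ... unused.
forecast.prophet_fit <- function(object, h = 1L, seed = NULL, ...) {
  h <- as.integer(h)
  if (h < 1L) stop("`h` must be >= 1")
  spec <- object$spec
  t_f <- object$n - 1 + seq_len(h)
  Xf <- prophet_design(t_f, object$T_scale, object$cp_ts,
                       spec$weekly_order, spec$yearly_order)
  point_s <- as.numeric(Xf %*% object$beta_scaled)

  ## interval: future changepoints at the historical frequency, slope
  ## changes from a Laplace with the empirical mean |delta|, plus Gaussian
  ## observation noise; 2.5%/97.5% sample quantiles.
  set.seed(if (is.null(seed)) spec$seed else seed)
  nsim <- spec$uncertainty_samples
  p_cp <- if (object$n > 0) length(object$cp_ts) / object$n else 0
  b_hat <- if (length(object$deltas)) mean(abs(object$deltas)) * object$T_scale / object$y_scale else 0
  sig_s <- sqrt(object$sigma2) / object$y_scale
  dev <- matrix(0, nrow = h, ncol = nsim)
  if (b_hat > 0 && p_cp > 0) {
    occur <- matrix(runif(h * nsim) < p_cp, nrow = h)
    mag <- matrix((rexp(h * nsim) - rexp(h * nsim)) * b_hat, nrow = h)
    slope <- matrix(apply(occur * mag, 2L, cumsum), nrow = h)  # scaled slope
    dev <- matrix(apply(slope / object$T_scale, 2L, cumsum), nrow = h)
  }
  eps <- matrix(rnorm(h * nsim, 0, sig_s), nrow = h)
  sims <- point_s + dev + eps
  lo <- apply(sims, 1L, quantile, probs = 0.025, names = FALSE)
  hi <- apply(sims, 1L, quantile, probs = 0.975, names = FALSE)
  point <- point_s * object$y_scale
  adm_forecast(date = forecast_dates(object, h), point = point,
               lo95 = pmin(lo * object$y_scale, point),
               hi95 = pmax(hi * object$y_scale, point), model = "prophet")
}
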