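# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written along a different computational route from
# the code it checks.

# Exact Gaussian log-likelihood of a zero-mean MA(q) series via the
# innovations algorithm on the theoretical autocovariances (Brockwell-Davis
# style), independent of the Kalman-filter path used in fitting.
ma_loglik_oracle <- function(y, theta, sigma2) {
  n <- length(y)
  q <- length(theta)
  psi <- c(1, theta)
  gamma <- vapply(0:q, function(h)
    sigma2 * sum(psi[1:(q + 1 - h)] * psi[(1 + h):(q + 1)]), 0)
  acvf <- function(h) if (abs(h) <= q) gamma[abs(h) + 1] else 0

  v <- numeric(n)          # innovation variances
  th <- matrix(0, n, n)    # innovation coefficients theta_{n,j}
  v[1] <- acvf(0)
  for (k in 1:(n - 1)) {
    for (j in 0:(k - 1)) {
      s <- acvf(k - j)
      if (j > 0) for (i in 0:(j - 1)) s <- s - th[j, j - i] * th[k, k - i] * v[i + 1]
      th[k, k - j] <- s / v[j + 1]
    }
    v[k + 1] <- acvf(0)
    for (i in 0:(k - 1)) v[k + 1] <- v[k + 1] - th[k, k - i]^2 * v[i + 1]
  }
  yhat <- numeric(n)
  for (k in 1:(n - 1)) {
    idx <- 1:min(k, q)
    yhat[k + 1] <- sum(th[k, idx] * (y[k + 1 - idx] - yhat[k + 1 - idx]))
  }
  -0.5 * sum(log(2 * pi * v)) - 0.5 * sum((y - yhat)^2 / v)
}

# Brute-force AUC: exhaustive enumeration of positive-negative pairs with
# half credit for ties.
auc_pairs_oracle <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  total <- 0
  for (xi in x) for (yj in y)
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  total / (length(x) * length(y))
}

# Small fixed daily series for I/O and windowing tests.
toy_series <- function(n = 30L, seed = 1L, start = "2021-03-01") {
  set.seed(seed)
  daily_series(as.Date(start) + 0:(n - 1L), rpois(n, 2))
}

scenario_series <- function(seed = 1L) {
  generate_series(asthma_scenario_config(seed),
                  as.Date("2016-01-01"), as.Date("2023-12-31"))
}
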