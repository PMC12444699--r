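Package: admitcast
Title: Forecasting Daily Asthma Hospital Admissions and Flagging High-Risk Days
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for next-day forecasting of daily hospital admission counts
    for pediatric asthma and for flagging days at high risk of an admission
    surge. Provides ARIMA (exact Gaussian maximum likelihood with an optional
    drift constant), additive innovations state-space exponential smoothing
    (ETS), and a piecewise-linear-trend model with Laplace-prior changepoints
    and Fourier seasonality, plus an ensemble that averages member point
    forecasts and interval limits. A rolling-origin backtest engine refits each
    model daily over configurable training-history windows and validation
    periods; evaluation includes median absolute percentage error, 95 percent
    interval coverage, ROC/AUC with DeLong confidence intervals, Youden-optimal
    operating points, and a 95th-percentile exceedance alert calibration. A
    negative-binomial synthetic-data generator emulates the seasonal,
    weekday, and pandemic-era structure of an eight-year pediatric asthma
    admission series so the full pipeline is testable without protected
    health records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
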