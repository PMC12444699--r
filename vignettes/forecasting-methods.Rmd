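---
title: "Methods: forecasting daily asthma admissions and flagging high-risk days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting daily asthma admissions and flagging high-risk days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admitcast)
```

## The problem

Daily pediatric asthma admission counts are small non-negative integers
(about two per day at a large children's hospital) with strong calendar
structure: a surge when school resumes in late summer, a June–July trough,
a Sunday–Tuesday weekday excess, and a roughly 50% level drop during the
first pandemic year. Two operational questions drive the design of this
package: *how many admissions should be expected tomorrow?* and *is
tomorrow likely to be a high-risk day* — one of the ~5% of days with an
extreme admission load?

`admitcast` answers both with a set of one-step-ahead forecasters, a
rolling-origin validation engine that mimics daily deployment, a
95th-percentile exceedance alert, and an evaluation suite. This vignette
records the modelling assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and
do not establish.

## The synthetic admission series

The real admission-level records behind series of this kind are protected
health information, so the package carries a generator
(`generate_series()`) whose calibrated configuration
(`asthma_scenario_config()`) emulates the published aggregate structure of
an eight-year (2016–2023) series. The model is

$$y_t \sim \mathrm{NegBin}(\mu_t, \;\text{size}=\kappa), \qquad
\log \mu_t = \beta_0 + f(\mathrm{doy}_t) + d_{\mathrm{dow}(t)}
 + \gamma\,\mathbb{1}[\text{school in session}]
 + \pi\,\mathbb{1}[\text{pandemic window}] + z_t - \sigma_z^2/2,$$

with $f$ an order-5 annual Fourier curve, $d$ seven weekday effects
(Mon–Sun), and $z_t$ a stationary AR(1) process
($\rho = 0.5$, marginal SD $\sigma_z = 0.2$) on the log intensity. The
AR(1) term is what makes one-step forecasting non-trivial: without it,
yesterday's count would carry no information beyond the calendar. The
$-\sigma_z^2/2$ correction keeps the marginal mean at the deterministic
intensity.

Calibration targets, fixed once by simulation: mean 1.91 admissions/day,
21.1% zero days, ~5% of days at 6+ admissions (slightly below 5%, so the
95th-percentile threshold lands at 6), September the highest month with
June and July lowest, Sunday–Tuesday totals each above Wednesday–Saturday,
and a 40–60% drop in the 2020 total against the 2016–2019 mean. The
chosen constants are: baseline 0.595 (log scale), school-term effect
+0.12 over Aug 15–May 31, pandemic shift −0.92 over
2020-03-11–2021-06-30, negative-binomial size 25.

Two deliberate departures from the published point estimates are worth
recording. First, the month-to-month gaps in the published totals
(September 639 vs November 604) are smaller than the sampling noise of a
count series of this size, so a generator matching the published
intensities exactly would reproduce the required orderings in only about
half of the seeds; the seasonal and weekday contrasts are therefore
sharpened modestly (e.g. +0.13 on September, −0.12 on June/July on the
log scale) so the orderings hold for essentially every seed. Second, a
pure Poisson model cannot jointly deliver mean 1.91 and a 5% tail at 6+
(its tail probability is ≈1.4%), which is why the generator is
negative-binomial with lognormal AR(1) mixing.

What passing tests on this generator show: that the pipeline's estimators,
backtest bookkeeping, thresholds and metrics behave correctly on data with
the right marginal structure, seasonality, weekday pattern, persistence
and overdispersion. What they do not show: performance on real admission
streams, which carry features the generator omits by design — weather and
pollution drivers, epidemic waves, holiday idiosyncrasies, coding-practice
drift, and per-patient covariates.

## Models

**ARIMA.** `fit_arima()` delegates to the exact Kalman-filter Gaussian
MLE in `stats::arima` (`method = "ML"`), which enforces stationary AR and
invertible MA roots through its internal reparameterisation. For $d=1$
the constant is fitted as a drift via a time regressor, because the plain
differenced model has no mean term; the reported `constant` is then the
mean daily change, and $h$-step forecasts increment by it once the MA
memory is exhausted. Order selection (`select_arima()`) minimises BIC
among candidates that pass a Ljung–Box residual check at 10 lags with
`fitdf = p + q` (gate at p > 0.05); if none pass, the BIC winner is
returned with a warning. The default candidate set is
(0,1,1), (0,1,2), (0,1,3), (1,1,1), (2,1,0), all with constant.

**ETS.** The additive innovations state space
($\mu_t = \ell + \phi b + s_{t-m}$, with the usual level/trend/seasonal
updates) is implemented directly (compiled filter in `src/`), since no
exponential-smoothing package is among the dependencies. Smoothing
parameters *and* initial states are estimated jointly by bounded
quasi-Newton (`L-BFGS-B`) on the concentrated likelihood
$n\log(\mathrm{SSE}/n)$, from a heuristic start plus two fixed alternative
starts; admissibility ($0<\beta<\alpha$, $0<\gamma<1-\alpha$,
$0.8\le\phi\le0.98$) is imposed by the box parameterisation
$\beta = \alpha\beta'$, $\gamma=(1-\alpha)\gamma'$. Seasonal initial
states are constrained to sum to zero ($m-1$ free values). The $h$-step
variance uses the additive-class multipliers
$c_j = \alpha + \beta\phi_j + \gamma\,\mathbb{1}[j \equiv 0 \ (\mathrm{mod}\ m)]$.
The seasonal period defaults to $m=7$: a 365-day additive seasonal state
would add 364 free initial values and is computationally degenerate at
these series lengths, so annual structure is left to the other model
classes. L-BFGS-B termination code 52 (line-search saturation) is treated
as convergence; it is the normal outcome when a warm-started refit begins
at the optimum.

**Piecewise-linear trend with Fourier seasonality.** The decomposable
model $y(t) = g(t) + s(t) + \varepsilon_t$ has trend
$g(t) = (k + \mathbf{a}(t)^\top\boldsymbol\delta)t + (m + \mathbf{a}(t)^\top\boldsymbol\gamma)$
with $S$ changepoints spread evenly over the first 80% of the history and
$\delta_j \sim \mathrm{Laplace}(0,\tau)$; $s(t)$ sums weekly (order 3)
and yearly (order 10) Fourier terms with unpenalized coefficients; the
holiday term is zero. With Gaussian errors the MAP estimate minimises
$\tfrac{1}{2\sigma^2}\|y - X\beta\|^2 + \tau^{-1}\|\boldsymbol\delta\|_1$,
i.e. an L1 penalty $\lambda = \sigma^2/\tau$ after rescaling — the noise
variance genuinely belongs in the penalty weight, and omitting it
over-penalises the trend by an order of magnitude on max-scaled count
data (the trend collapses to a single line and extrapolates the
pandemic-recovery slope into the validation year with a ~20% upward
bias). $\sigma^2$ is estimated alongside by a 3-step fixed-point
iteration. The solver profiles the unpenalized block out exactly by QR
and runs coordinate descent only on the residualized changepoint block,
finishing each round with an exact KKT solve on the active set; the KKT
residual decides convergence. Defaults: $S=25$, $\tau=0.05$, both
configurable; on windows shorter than two full years the yearly block is
dropped (there is no identifiable annual cycle to fit).

Forecast intervals for this model are simulated, since the reference
ecosystem's interval construction is not documented in analytic form:
future changepoints arrive as Bernoulli events at the historical
frequency $S/T$, each with a Laplace slope change of empirical scale
$\overline{|\hat\delta|}$, plus Gaussian observation noise; the 2.5% and
97.5% sample quantiles over `uncertainty_samples` (default 300) seeded
draws form the interval. This is a documented reimplementation choice,
not a claim about the original package's internals.

**Ensemble.** The per-date arithmetic mean of the member point forecasts;
interval limits are the means of the member limits (hence the ensemble
width is the mean member width). No weighting is attempted.

Intervals from all models are Gaussian or sample quantiles and may extend
below zero on count data; they are not truncated, so that the coverage
metric evaluates the models as fit. A truncated display is a presentation
choice, not a modelling one.

## Rolling-origin validation

`run_backtest()` fixes model *structure* once on the initial training
window (orders via `select_arima()`, ETS form via `select_ets()`, when
`"auto"` is requested), then re-estimates *parameters* every
`refit_cadence` days (default 1) on a window chosen by `window_policy`,
and records exactly one one-step forecast per validation day. The window
policies make an inherent ambiguity explicit: sweeping 1–7-year training
lengths while "always using the most recent 365 days" cannot both hold,
so `"sliding-full"` (default) slides a window of the initial training
length, `"sliding-365"` implements the literal most-recent-365-days rule,
and `"expanding"` grows from the initial training start. Re-*selection*
of structure is deliberately not repeated daily: it would multiply cost
~5-fold and a single chosen specification per class is the deployment
model being simulated.

Failed refits (non-convergence on a pathological window) fall back to the
previous day's parameters with a warning, and abort the run if they exceed
20% of days. Constant windows — e.g. an all-zero stretch under a severe
pandemic shift — return a degenerate deterministic fit that forecasts the
constant with a zero-width interval rather than erroring, so backtests
spanning such periods complete. Warm starts (previous day's parameters
for ETS, coefficients for the penalized trend model, `init` for ARIMA)
keep the daily refit loop fast without changing the estimates; for the
trend model the design matrix of a sliding window is cached, since it
depends only on the window length.

Temporal causality is structural (the window ends the day before the
forecast date) and verified by a mutation test: perturbing any observation
at or after date $d$ leaves the forecast for $d$ unchanged.

## High-risk calibration and metrics

The observed threshold is the smallest integer $t$ with
$\Pr(\text{count} \ge t) \le 1 - 0.95$ over the history — an integer
exceedance rule rather than an interpolated quantile, so "$t$ or more
admissions" is reproduced exactly, and the threshold is monotone in the
percentile. Prediction-side thresholds use the linear-interpolation
quantile of each model's continuous predictions, with strict `>`
classification. By default the calibration consumes one-step predictions
over the training history, so no validation information enters it.

The accuracy metrics are the median absolute percentage error and the
inclusive-endpoint 95% interval coverage. About a fifth of all days have
zero admissions, where a percentage error is undefined; this is the
single largest unstated analytic choice in the problem, so it is an
explicit policy: the default excludes zero-actual days and reports the
exclusion count, and a `denominator-max-1` alternative keeps every day.
Discrimination metrics score the continuous point forecasts against the
observed-exceedance labels: AUC is the tie-aware Mann–Whitney
probability with a DeLong-variance 95% CI, the operating point maximises
Youden's $J$ (ties broken by higher sensitivity, then lower threshold),
and PPV/NPV are reported both at the Youden cut and at the 5% calibrated
alert threshold, since either convention is defensible.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that keep the full
pipeline honest while remaining comfortable on a single CPU: coverage
checks use 2,000 one-step forecasts at fixed parameters; parameter
recovery uses $n = 3{,}000$ with 3-standard-error bands from the observed
information; the ensemble property and the acceptance backtest use the
headline design — three years of training, the full final year (365 days)
of daily refits, all three members plus the ensemble — per seed. The KPSS
implementation is checked to $10^{-6}$ against reference values computed
once with an independent implementation; ROC/AUC against both an
exhaustive pair-enumeration oracle and the `pROC` package.

Known limitations: the forecasters are Gaussian on counts (no count
likelihoods), interval coverage near zero counts leans on that
approximation; the alert threshold is a marginal percentile, not a
cost-weighted decision rule; and none of the models anticipates
out-of-calendar shocks — a sudden epidemic wave enters the fits only
after it appears in the data, which is precisely what the pandemic-era
backtest configurations are for.
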