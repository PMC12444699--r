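#include <Rcpp.h>
using namespace Rcpp;

// One pass of the additive innovations state-space (ETS) recursions.
//   mu_t = l + phi*b + s_{t-m};  e_t = y_t - mu_t
//   l <- l + phi*b + alpha*e;  b <- phi*b + beta*e;  s_{t} <- s_{t-m} + gamma*e
// Seasonal states are kept in a circular buffer: s0[j] is the seasonal
// component applying at observation j+1. Returns one-step residuals, fitted
// values, SSE and the end-of-sample states (the buffer entry ((n + h - 1)
// mod m) is the seasonal for forecast step h).
// [[Rcpp::export]]
List ets_filter_cpp(NumericVector y, double alpha, double beta, double gamma,
                    double phi, double l0, double b0, NumericVector s0,
                    bool has_trend, bool has_seasonal) {
  int n = y.size();
  int m = has_seasonal ? s0.size() : 0;
  NumericVector e(n), fitted(n);
  std::vector<double> s(m);
  for (int j = 0; j < m; ++j) s[j] = s0[j];
  double l = l0, b = b0, sse = 0.0;
  for (int t = 0; t < n; ++t) {
    double seas = has_seasonal ? s[t % m] : 0.0;
    double damped = has_trend ? phi * b : 0.0;
    double mu = l + damped + seas;
    double err = y[t] - mu;
    fitted[t] = mu;
    e[t] = err;
    sse += err * err;
    l = l + damped + alpha * err;
    if (has_trend) b = damped + beta * err;
    if (has_seasonal) s[t % m] = seas + gamma * err;
  }
  return List::create(_["residuals"] = e, _["fitted"] = fitted,
                      _["sse"] = sse, _["level"] = l, _["trend"] = b,
                      _["seasonal"] = NumericVector(s.begin(), s.end()),
                      _["n"] = n);
}

// Simulate from the same recursions with supplied innovations e.
// [[Rcpp::export]]
NumericVector ets_simulate_cpp(NumericVector e, double alpha, double beta,
                               double gamma, double phi, double l0, double b0,
                               NumericVector s0, bool has_trend,
                               bool has_seasonal) {
  int n = e.size();
  int m = has_seasonal ? s0.size() : 0;
  NumericVector y(n);
  std::vector<double> s(m);
  for (int j = 0; j < m; ++j) s[j] = s0[j];
  double l = l0, b = b0;
  for (int t = 0; t < n; ++t) {
    double seas = has_seasonal ? s[t % m] : 0.0;
    double damped = has_trend ? phi * b : 0.0;
    double mu = l + damped + seas;
    y[t] = mu + e[t];
    l = l + damped + alpha * e[t];
    if (has_trend) b = damped + beta * e[t];
    if (has_seasonal) s[t % m] = seas + gamma * e[t];
  }
  return y;
}
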