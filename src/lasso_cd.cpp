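#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for
//   1/2 ||y - X b||^2 + lambda * sum_{j in pen} |b_j|
// with soft-thresholding on penalized coordinates and exact minimisation on
// the rest. Returns the coefficient vector after convergence of the sweep
// (max absolute coefficient change below tol relative to the largest
// coefficient) or max_sweeps.
// [[Rcpp::export]]
NumericVector lasso_cd_cpp(NumericMatrix X, NumericVector y, double lambda,
                           LogicalVector pen, NumericVector beta0,
                           int max_sweeps, double tol) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> xtx(p), r(n);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) fit += X(i, j) * beta[j];
    r[i] = y[i] - fit;
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double delta_max = 0.0, beta_max = 1.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] == 0.0) continue;
      double bj = beta[j], rho = xtx[j] * bj;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      double bnew;
      if (pen[j]) {
        double a = std::fabs(rho) - lambda;
        bnew = a > 0.0 ? (rho > 0.0 ? a : -a) / xtx[j] : 0.0;
      } else {
        bnew = rho / xtx[j];
      }
      if (bnew != bj) {
        double d = bnew - bj;
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        beta[j] = bnew;
        if (std::fabs(d) > delta_max) delta_max = std::fabs(d);
      }
      if (std::fabs(beta[j]) > beta_max) beta_max = std::fabs(beta[j]);
    }
    if (delta_max < tol * beta_max) break;
  }
  return beta;
}
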