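#include <Rcpp.h>
using namespace Rcpp;

// Sequential Gibbs scan over marker effects with incremental residual
// updates. Uses R's RNG so chains are reproducible from set.seed() and the
// draws coincide with the R-level update_marker_effect() on a shared
// stream (asserted in the test suite).

// [[Rcpp::export]]
List marker_sweep_cpp(const NumericMatrix& X, const NumericVector& w,
                      const NumericVector& xtwx, NumericVector resid,
                      NumericVector beta, const NumericVector& prior_var,
                      double sigma2_e) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector e = clone(resid), b = clone(beta);
  for (int k = 0; k < m; ++k) {
    const double* xk = &X(0, k);
    double rhs = 0.0;
    const double bk = b[k];
    for (int i = 0; i < n; ++i) rhs += w[i] * xk[i] * (e[i] + xk[i] * bk);
    rhs /= sigma2_e;
    const double v = 1.0 / (xtwx[k] / sigma2_e + 1.0 / prior_var[k]);
    const double bnew = R::rnorm(v * rhs, std::sqrt(v));
    const double diff = bk - bnew;
    for (int i = 0; i < n; ++i) e[i] += xk[i] * diff;
    b[k] = bnew;
  }
  return List::create(_["beta"] = b, _["resid"] = e);
}

// Collapsed BayesB scan: Bernoulli indicator with beta_k integrated out,
// then the effect draw for included markers. Draw order (runif then rnorm)
// matches update_bayesB_indicator() in R.

// [[Rcpp::export]]
List bayesb_sweep_cpp(const NumericMatrix& X, const NumericVector& w,
                      const NumericVector& xtwx, NumericVector resid,
                      NumericVector beta, IntegerVector delta,
                      const NumericVector& sigma2_beta_k, double sigma2_e,
                      double pi) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector e = clone(resid), b = clone(beta);
  IntegerVector d = clone(delta);
  const double log_odds0 = (pi > 0.0 && pi < 1.0)
    ? std::log(pi / (1.0 - pi)) : 0.0;
  for (int k = 0; k < m; ++k) {
    const double* xk = &X(0, k);
    double rhs = 0.0;
    const double bk = b[k];
    for (int i = 0; i < n; ++i) rhs += w[i] * xk[i] * (e[i] + xk[i] * bk);
    rhs /= sigma2_e;
    const double v0 = sigma2_beta_k[k];
    const double vpost = 1.0 / (xtwx[k] / sigma2_e + 1.0 / v0);
    const double log_bf = 0.5 * std::log(vpost / v0) + 0.5 * rhs * rhs * vpost;
    double p1;
    if (pi == 0.0)      p1 = 1.0;
    else if (pi == 1.0) p1 = 0.0;
    else                p1 = 1.0 / (1.0 + std::exp(log_odds0 - log_bf));
    const int dnew = (R::unif_rand() < p1) ? 1 : 0;
    const double bnew = (dnew == 1) ? R::rnorm(vpost * rhs, std::sqrt(vpost))
                                    : 0.0;
    const double diff = bk - bnew;
    if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += xk[i] * diff;
    b[k] = bnew;
    d[k] = dnew;
  }
  return List::create(_["beta"] = b, _["resid"] = e, _["delta"] = d);
}
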