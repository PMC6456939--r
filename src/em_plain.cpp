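#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a finite mixture of right-censored geometric distributions.
// Support starts at 0; observed entries contribute p*(1-p)^y, censored
// entries (delta == 0) contribute (1-p)^(T+1). All likelihood work is done
// in log space with a row-wise log-sum-exp.
//
// Returns the final parameters, responsibilities, per-iteration observed-
// data log-likelihood and convergence state. Proportions are floored at
// 1e-8 and renormalized; success probabilities clamped to [1e-12, 1-1e-12].
// A component with zero uncensored weight raises an error (collapse).

// [[Rcpp::export(name = ".em_plain_cpp")]]
List em_plain_cpp(NumericVector y, IntegerVector delta, double T,
                  NumericVector pi0, NumericVector p0,
                  int max_iter, double tol) {
  const int n = y.size();
  const int g = p0.size();
  const bool censored_any = !NumericVector::is_na(T);
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> p(p0.begin(), p0.end());
  NumericMatrix tau(n, g);
  NumericVector trace(max_iter);
  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    // E-step
    std::vector<double> logpi(g), logp(g), log1mp(g);
    for (int j = 0; j < g; ++j) {
      logpi[j] = std::log(pi[j]);
      logp[j] = std::log(p[j]);
      log1mp[j] = std::log1p(-p[j]);
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      double lc[64];  // g is small in practice; guard below
      double *lrow = (g <= 64) ? lc : (double *) R_alloc(g, sizeof(double));
      for (int j = 0; j < g; ++j) {
        double l = (delta[i] == 1)
          ? logp[j] + y[i] * log1mp[j]
          : (T + 1.0) * log1mp[j];
        l += logpi[j];
        lrow[j] = l;
        if (l > mx) mx = l;
      }
      double s = 0.0;
      for (int j = 0; j < g; ++j) s += std::exp(lrow[j] - mx);
      double lse = mx + std::log(s);
      ll += lse;
      for (int j = 0; j < g; ++j) tau(i, j) = std::exp(lrow[j] - lse);
    }
    trace[it] = ll;
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1.0)) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step
    for (int j = 0; j < g; ++j) {
      double sw = 0.0, num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        const double t = tau(i, j);
        sw += t;
        if (delta[i] == 1) {
          num += t;
          den += t * (1.0 + y[i]);
        } else {
          den += t * (T + 1.0);
        }
      }
      if (num <= 0.0)
        stop("component collapse: a component has zero uncensored weight");
      pi[j] = sw / n;
      double pj = num / den;
      if (pj < 1e-12) pj = 1e-12;
      if (pj > 1.0 - 1e-12) pj = 1.0 - 1e-12;
      p[j] = pj;
    }
    double s = 0.0;
    for (int j = 0; j < g; ++j) { if (pi[j] < 1e-8) pi[j] = 1e-8; s += pi[j]; }
    for (int j = 0; j < g; ++j) pi[j] /= s;
    if (!censored_any) { /* T unused when all delta == 1 */ }
  }

  int n_iter = std::min(it + 1, max_iter);
  return List::create(_["pi"] = NumericVector(pi.begin(), pi.end()),
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["tau"] = tau,
                      _["loglik"] = ll,
                      _["trace"] = trace[Range(0, n_iter - 1)],
                      _["converged"] = converged,
                      _["n_iter"] = n_iter);
}
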