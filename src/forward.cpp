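#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Scaled forward recursion for a hidden Markov model.
// logdens: n x S matrix of per-observation per-state log emission densities.
// Returns the total log-likelihood.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta) {
  const int n = logdens.nrow(), S = logdens.ncol();
  std::vector<double> alpha(S), tmp(S);
  double ll = 0.0;
  for (int s = 0; s < S; ++s)
    tmp[s] = std::log(delta[s]) + logdens(0, s);
  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      for (int s = 0; s < S; ++s) {
        double a = 0.0;
        for (int r = 0; r < S; ++r) a += alpha[r] * Gamma(r, s);
        tmp[s] = (a > 0.0 ? std::log(a) : -INFINITY) + logdens(t, s);
      }
    }
    double m = *std::max_element(tmp.begin(), tmp.end());
    if (!std::isfinite(m)) return -INFINITY;
    double sum = 0.0;
    for (int s = 0; s < S; ++s) { alpha[s] = std::exp(tmp[s] - m); sum += alpha[s]; }
    ll += m + std::log(sum);
    for (int s = 0; s < S; ++s) alpha[s] /= sum;
  }
  return ll;
}
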