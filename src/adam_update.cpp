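#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update for one parameter tensor. The caller guarantees
// p, m and v are uniquely referenced (deep-copied at training start), so
// mutating them here is safe and avoids three full allocations per
// parameter per minibatch.

// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector p, NumericVector g, NumericVector m,
                         NumericVector v, double lr, double beta1,
                         double beta2, double eps, int t) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
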