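#include <Rcpp.h>
#include <cmath>

// In-place Adam update of one parameter tensor. The caller guarantees
// exclusive ownership of p, m and v (they are deep-copied once at the
// start of training), so mutating them here is safe and avoids
// reallocating three ~40 MB matrices on every minibatch.

// [[Rcpp::export(name = ".adam_update")]]
void adam_update(Rcpp::NumericVector p, Rcpp::NumericVector g,
                 Rcpp::NumericVector m, Rcpp::NumericVector v,
                 double lr, double beta1, double beta2, double eps,
                 double corr1, double corr2) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n) {
    Rcpp::stop("adam_update: length mismatch");
  }
  double *pp = p.begin(), *pg = g.begin(), *pm = m.begin(), *pv = v.begin();
  const double inv_c1 = 1.0 / corr1, inv_c2 = 1.0 / corr2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double mi = beta1 * pm[i] + (1.0 - beta1) * gi;
    const double vi = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr * (mi * inv_c1) / (std::sqrt(vi * inv_c2) + eps);
  }
}
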