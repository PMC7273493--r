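#include <Rcpp.h>
using namespace Rcpp;

// Per-sample NLMS adaptive noise cancellation.
//
// d: primary input (signal + coupled noise), x: reference input (noise only).
// For each sample n the tap vector holds the most recent `order` reference
// samples (zero-padded before the first `order` samples):
//   y(n) = w(n)' x(n)
//   e(n) = d(n) - y(n)
//   w(n+1) = w(n) + mu / (x(n)'x(n) + psi) * e(n) * x(n)
// Everything stays in double precision; the tap energy is recomputed from the
// buffer each sample (no running-sum drift).
// [[Rcpp::export]]
NumericVector nlms_core(NumericVector d, NumericVector x,
                        double mu, double psi, int order) {
  const R_xlen_t n = d.size();
  NumericVector e(n);
  std::vector<double> w(order, 0.0);
  // padded copy of the reference so taps[j] = x(i - j) needs no shifting
  std::vector<double> xp(n + order, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) xp[order + i] = x[i];

  for (R_xlen_t i = 0; i < n; ++i) {
    const double *taps = &xp[order + i]; // taps[-j] = x(i - j)
    double y = 0.0, energy = 0.0;
    for (int j = 0; j < order; ++j) {
      const double t = taps[-j];
      y += w[j] * t;
      energy += t * t;
    }
    const double err = d[i] - y;
    e[i] = err;
    const double g = mu * err / (energy + psi);
    for (int j = 0; j < order; ++j) w[j] += g * taps[-j];
  }
  return e;
}
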