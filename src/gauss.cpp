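#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Fast Gaussian streams for the signal generator. Seeds are drawn from the
// R RNG at the call site, so results remain reproducible via set.seed().

// [[Rcpp::export]]
NumericVector gauss_vec(double n, double sd, double seed) {
  R_xlen_t len = (R_xlen_t)n;
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N(0.0, sd);
  NumericVector y(len);
  for (R_xlen_t i = 0; i < len; ++i) y[i] = N(rng);
  return y;
}

// White Gaussian noise through the AR(2) resonator in one fused pass:
// y[t] = scale * e[t] - a1 y[t-1] - a2 y[t-2], discarding `warm` warm-up
// samples.
// [[Rcpp::export]]
NumericVector gauss_ar2(double n, double a1, double a2, double scale,
                        double warm, double seed) {
  R_xlen_t len = (R_xlen_t)n, w = (R_xlen_t)warm;
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N(0.0, 1.0);
  NumericVector y(len);
  double y1 = 0.0, y2 = 0.0;
  for (R_xlen_t i = 0; i < w; ++i) {
    double v = scale * N(rng) - a1 * y1 - a2 * y2;
    y2 = y1; y1 = v;
  }
  for (R_xlen_t i = 0; i < len; ++i) {
    double v = scale * N(rng) - a1 * y1 - a2 * y2;
    y[i] = v;
    y2 = y1; y1 = v;
  }
  return y;
}
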