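#include <Rcpp.h>
using namespace Rcpp;

// Second-order all-pole (resonator) filter: y[t] = x[t] - a1 y[t-1] - a2 y[t-2].
// Hot loop of the synthetic-EEG generator.
// [[Rcpp::export]]
NumericVector ar2_filter(NumericVector x, double a1, double a2) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  double y1 = 0.0, y2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i] - a1 * y1 - a2 * y2;
    y[i] = v;
    y2 = y1;
    y1 = v;
  }
  return y;
}
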