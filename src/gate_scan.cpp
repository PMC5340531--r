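#include <Rcpp.h>
using namespace Rcpp;

// Exponential-Euler scan for one gating variable under a clamped waveform.
// x[i] = xinf[i-1] + (x[i-1] - xinf[i-1]) * a[i-1], a = exp(-dt/tau),
// with (xinf, tau) evaluated at the clamped voltage of the left sample.
// Exact for piecewise-constant voltage; unconditionally stable.
// [[Rcpp::export(name = ".gate_scan")]]
NumericVector gate_scan(NumericVector xinf, NumericVector a, double x0) {
  R_xlen_t n = xinf.size();
  if (a.size() != n) stop("xinf and a must have equal length");
  NumericVector x(n);
  x[0] = x0;
  for (R_xlen_t i = 1; i < n; ++i) {
    x[i] = xinf[i - 1] + (x[i - 1] - xinf[i - 1]) * a[i - 1];
  }
  return x;
}
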