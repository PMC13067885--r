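// Direct-form II transposed IIR filter with explicit initial state.
// The zero-phase (forward-backward) wrapper lives in R; this is the
// per-pass inner loop.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cppIirFilter")]]
NumericVector cppIirFilter(NumericVector b, NumericVector a,
                           NumericVector x, NumericVector zi) {
  const int nb = b.size();
  const R_xlen_t n = x.size();
  const int nz = nb - 1;
  double zbuf[32];
  double bc[32], ac[32];
  if (nb > 32) stop("filter order too high");
  for (int k = 0; k < nb; ++k) {
    bc[k] = b[k];
    ac[k] = a[k];
  }
  for (int k = 0; k < nz; ++k) zbuf[k] = k < zi.size() ? zi[k] : 0.0;
  NumericVector y(n);
  const double *px = REAL(x);
  double *py = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = px[i];
    const double yi = bc[0] * xi + (nz ? zbuf[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      zbuf[k] = bc[k + 1] * xi + zbuf[k + 1] - ac[k + 1] * yi;
    if (nz) zbuf[nz - 1] = bc[nz] * xi - ac[nz] * yi;
    py[i] = yi;
  }
  return y;
}
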