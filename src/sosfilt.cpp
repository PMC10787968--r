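#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections in direct form II transposed, with explicit
// filter state so that streaming (frame-by-frame) filtering is bit-identical
// to filtering the whole record in one call.
//
// sos: n_sections x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// zi:  n_sections x 2 state matrix (pass zeros for rest state).

// [[Rcpp::export]]
List sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  if (zi.nrow() != ns || zi.ncol() != 2)
    stop("state matrix must be n_sections x 2");
  NumericVector y = clone(x);
  NumericMatrix z = clone(zi);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = z(s, 0), z2 = z(s, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi + z2 - a1 * yi;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    z(s, 0) = z1;
    z(s, 1) = z2;
  }
  return List::create(_["y"] = y, _["zi"] = z);
}

// Column-wise RMS over consecutive non-overlapping bins of `width` samples.
// x is a time x channels matrix; trailing partial bin is dropped.

// [[Rcpp::export]]
NumericMatrix bin_rms_cpp(NumericMatrix x, int width) {
  const int n = x.nrow(), nc = x.ncol();
  const int nb = n / width;
  NumericMatrix out(nb, nc);
  for (int c = 0; c < nc; ++c) {
    for (int b = 0; b < nb; ++b) {
      double acc = 0.0;
      const int off = b * width;
      for (int i = 0; i < width; ++i) {
        const double v = x(off + i, c);
        acc += v * v;
      }
      out(b, c) = std::sqrt(acc / width);
    }
  }
  return out;
}
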