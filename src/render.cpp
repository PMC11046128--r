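// Hot path of the field renderer: additive Gaussian stamps and elongated
// strokes composited into a cell window in one call per channel.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

void stamp_one(NumericMatrix& win, double row, double col, double sigma,
               double amp) {
  const int n = win.nrow(), m = win.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  const int cr = (int)std::lround(row), cc = (int)std::lround(col);
  if (cr + r < 1 || cr - r > n || cc + r < 1 || cc - r > m) return;
  const int r0 = std::max(1, cr - r), r1 = std::min(n, cr + r);
  const int c0 = std::max(1, cc - r), c1 = std::min(m, cc + r);
  const double inv = 1.0 / (2.0 * sigma * sigma);
  for (int c = c0; c <= c1; ++c) {
    const double dc2 = (c - col) * (c - col);
    for (int rr = r0; rr <= r1; ++rr) {
      const double d2 = (rr - row) * (rr - row) + dc2;
      win(rr - 1, c - 1) += amp * std::exp(-d2 * inv);
    }
  }
}

}  // namespace

// Stamps k primitives into `base` (copied). Primitives with len <= 0 are
// single Gaussian puncta; len > 0 are strokes of Gaussian stamps spaced
// 0.8 * sigma apart with the per-stamp amplitude damping of the stroke
// renderer. Coordinates are 1-based (row, col) in window space.
// [[Rcpp::export(name = ".stamp_primitives_cpp")]]
NumericMatrix stamp_primitives_cpp(NumericMatrix base, NumericVector row,
                                   NumericVector col, NumericVector angle,
                                   NumericVector len, NumericVector sigma,
                                   NumericVector amp) {
  NumericMatrix win = clone(base);
  const int k = row.size();
  for (int i = 0; i < k; ++i) {
    if (len[i] <= 0) {
      stamp_one(win, row[i], col[i], sigma[i], amp[i]);
    } else {
      const int steps = std::max(2, (int)std::ceil(len[i] / (0.8 * sigma[i])));
      const double a = amp[i] / (1.0 + 0.15 * steps / 4.0);
      const double s = std::sin(angle[i]), c = std::cos(angle[i]);
      for (int j = 0; j < steps; ++j) {
        const double t = -len[i] / 2.0 + len[i] * j / (steps - 1.0);
        stamp_one(win, row[i] + t * s, col[i] + t * c, sigma[i], a);
      }
    }
  }
  return win;
}
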