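// Sample entropy per segment (matrix column), Chebyshev distance,
// tolerance r = r_factor * SD of the segment.  Degenerate segments
// (zero SD, or no template matches) return 0 by convention.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector sampen_cols(NumericMatrix S, int m, double r_factor) {
  int w = S.nrow(), n_seg = S.ncol();
  NumericVector out(n_seg);
  for (int c = 0; c < n_seg; ++c) {
    NumericMatrix::Column x = S(_, c);
    double mean = 0.0;
    for (int i = 0; i < w; ++i) mean += x[i];
    mean /= w;
    double ss = 0.0;
    for (int i = 0; i < w; ++i) ss += (x[i] - mean) * (x[i] - mean);
    double sdv = std::sqrt(ss / (w - 1));
    if (sdv <= 0.0 || w <= m + 1) {
      out[c] = 0.0;
      continue;
    }
    double r = r_factor * sdv;
    long long B = 0, A = 0;  // matches of length m and m+1
    int N = w - m;           // number of length-m templates (use first N-1 vs rest)
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double dk = std::fabs(x[i + k] - x[j + k]);
          if (dk > d) d = dk;
        }
        if (d <= r) {
          ++B;
          if (i + m < w && j + m < w &&
              std::fabs(x[i + m] - x[j + m]) <= r) {
            ++A;
          }
        }
      }
    }
    out[c] = (A > 0 && B > 0) ? -std::log((double)A / (double)B) : 0.0;
  }
  return out;
}
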