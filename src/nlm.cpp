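// Non-local means for a single 2D image: for every pixel, a weighted
// average over the search ("big") window, weights a Gaussian of the mean
// squared difference between local ("small") patches.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_nlm(const Rcpp::NumericMatrix& img, int big,
                            int small, double h, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int br = big / 2, sr = small / 2;
  const double h2 = h * h, two_sig2 = 2.0 * sigma * sigma;
  const int npatch = small * small;
  Rcpp::NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int qj = std::max(0, j - br); qj <= std::min(W - 1, j + br); ++qj) {
        for (int qi = std::max(0, i - br); qi <= std::min(H - 1, i + br); ++qi) {
          if (qi == i && qj == j) continue;
          double d2 = 0.0; // mean squared patch difference (clamped borders)
          for (int v = -sr; v <= sr; ++v)
            for (int u = -sr; u <= sr; ++u) {
              const double a = img(clampi(i + u, 0, H - 1), clampi(j + v, 0, W - 1));
              const double b = img(clampi(qi + u, 0, H - 1), clampi(qj + v, 0, W - 1));
              d2 += (a - b) * (a - b);
            }
          d2 /= npatch;
          const double w = std::exp(-std::max(d2 - two_sig2, 0.0) / h2);
          wmax = std::max(wmax, w);
          wsum += w;
          acc += w * img(qi, qj);
        }
      }
      // the centre pixel gets the maximum neighbour weight (standard NLM)
      const double wc = wmax > 0 ? wmax : 1.0;
      out(i, j) = (acc + wc * img(i, j)) / (wsum + wc);
    }
  }
  return out;
}
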