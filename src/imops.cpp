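// Small image-processing kernels used by the phantom geometry module.
#include <Rcpp.h>
#include <vector>

// 4-connected component labelling of a logical mask; labels are 1-based in
// raster-scan discovery order, 0 = background.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_components(const Rcpp::LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          const int qi = pi + di[d], qj = pj + dj[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}
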