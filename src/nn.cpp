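// Minimal 2D CNN kernels backing the U-Net / ResU-Net denoisers: same-size
// convolution via im2col + GEMM with exact backward passes, 2x2 max
// pooling, and nearest-neighbour 2x upsampling.  Tensors are R arrays of
// dim (H, W, C) mapped onto arma::cube; weights are (Cout x k*k*Cin)
// matrices whose column layout matches im2col (u + v*k + c*k*k).
//
// The patch matrix is laid out (H*W x k*k*Cin) so that the inner copy
// loops write contiguous column segments (single-core friendly).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// col(i + j*H, u + v*k + c*k*k) = x(i+u-pad, j+v-pad, c), zero-padded
static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = (k - 1) / 2;
  mat col(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int v = 0; v < k; ++v)
      for (int u = 0; u < k; ++u) {
        double* cp = col.colptr(u + v * k + c * k * k);
        const int i0 = std::max(0, pad - u), i1 = std::min(H, H + pad - u);
        for (int j = 0; j < W; ++j) {
          const int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          // rows i0..i1-1 of output column j come from x(i+u-pad, sj, c)
          std::memcpy(cp + (size_t)j * H + i0,
                      xs + (size_t)sj * H + (i0 + u - pad),
                      (i1 - i0) * sizeof(double));
        }
      }
  }
  return col;
}

static cube col2im(const mat& col, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xs = x.slice_memptr(c);
    for (int v = 0; v < k; ++v)
      for (int u = 0; u < k; ++u) {
        const double* cp = col.colptr(u + v * k + c * k * k);
        const int i0 = std::max(0, pad - u), i1 = std::min(H, H + pad - u);
        for (int j = 0; j < W; ++j) {
          const int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = xs + (size_t)sj * H + (i0 + u - pad);
          const double* src = cp + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  mat out = im2col(x, k) * w.t();      // (H*W x Cout)
  out.each_row() += b.t();
  cube y(out.memptr(), H, W, Cout);    // column-major reinterpret
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  // dy as (H*W x Cout) without copy of structure semantics
  const mat dyM(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  const mat col = im2col(x, k);
  mat dW = dyM.t() * col;              // (Cout x k*k*C)
  vec db = sum(dyM, 0).t();
  cube dx = col2im(dyM * w, H, W, C, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  ucube idx(h, w, C); // linear index into the input slice
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            if (x(si, sj, c) > best) { best = x(si, sj, c); bi = si + sj * H; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dy, const arma::ucube& idx,
                          int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        dx.slice(c)(idx(i, j, c)) += dy(i, j, c);
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;     y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
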