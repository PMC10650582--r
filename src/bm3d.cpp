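// Two-pass BM3D for a single 2D image.
//
// Pass 1: block matching on the noisy image, orthonormal 3D DCT of each
// group, hard threshold at 2.7*sigma, weighted aggregation -> basic
// estimate.  Pass 2: re-matching on the basic estimate, empirical Wiener
// shrinkage of the noisy group using the basic group's spectrum.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat dct_matrix(int n) {
  mat D(n, n);
  const double c0 = std::sqrt(1.0 / n), c = std::sqrt(2.0 / n);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      D(k, j) = (k == 0 ? c0 : c) * std::cos(M_PI * (2 * j + 1) * k / (2.0 * n));
  return D;
}

struct Match { double d; int i, j; };

// collect up to gmax best-matching BxB blocks for reference (ri, rj),
// matching performed on `ref_img`
static std::vector<Match> find_matches(const mat& ref_img, int ri, int rj,
                                       int B, int N, int gmax) {
  const int H = ref_img.n_rows, W = ref_img.n_cols, nr = N / 2;
  const mat rb = ref_img.submat(ri, rj, ri + B - 1, rj + B - 1);
  std::vector<Match> ms;
  for (int j = std::max(0, rj - nr); j <= std::min(W - B, rj + nr); ++j)
    for (int i = std::max(0, ri - nr); i <= std::min(H - B, ri + nr); ++i) {
      const double d = accu(square(ref_img.submat(i, j, i + B - 1, j + B - 1) - rb));
      ms.push_back({d / (B * B), i, j});
    }
  const size_t g = std::min<size_t>(gmax, ms.size());
  std::partial_sort(ms.begin(), ms.begin() + g, ms.end(),
                    [](const Match& a, const Match& b) { return a.d < b.d; });
  ms.resize(g);
  return ms;
}

// forward 3D DCT of group (in place): 2D per slice then 1D along slices
static void dct3(cube& G, const mat& D2, const mat& D1, bool inverse) {
  const uword g = G.n_slices;
  if (!inverse) {
    for (uword s = 0; s < g; ++s) G.slice(s) = D2 * G.slice(s) * D2.t();
    for (uword i = 0; i < G.n_rows; ++i)
      for (uword j = 0; j < G.n_cols; ++j) {
        vec v = G.tube(i, j);
        G.tube(i, j) = D1 * v;
      }
  } else {
    for (uword i = 0; i < G.n_rows; ++i)
      for (uword j = 0; j < G.n_cols; ++j) {
        vec v = G.tube(i, j);
        G.tube(i, j) = D1.t() * v;
      }
    for (uword s = 0; s < g; ++s) G.slice(s) = D2.t() * G.slice(s) * D2;
  }
}

// [[Rcpp::export]]
arma::mat cpp_bm3d(const arma::mat& img, int B, int N, double sigma,
                   int step, int gmax, double lambda) {
  const int H = img.n_rows, W = img.n_cols;
  const mat D2 = dct_matrix(B);
  std::vector<mat> D1(gmax + 1);
  for (int g = 1; g <= gmax; ++g) D1[g] = dct_matrix(g);

  std::vector<int> ris, rjs;
  for (int i = 0; i + B <= H; i += step) ris.push_back(i);
  if (ris.empty() || ris.back() != H - B) ris.push_back(H - B);
  for (int j = 0; j + B <= W; j += step) rjs.push_back(j);
  if (rjs.empty() || rjs.back() != W - B) rjs.push_back(W - B);

  auto run_pass = [&](const mat& match_on, const mat* basic) -> mat {
    mat num(H, W, fill::zeros), den(H, W, fill::zeros);
    for (int rj : rjs)
      for (int ri : ris) {
        auto ms = find_matches(match_on, ri, rj, B, N, gmax);
        const int g = static_cast<int>(ms.size());
        cube Gn(B, B, g);
        for (int s = 0; s < g; ++s)
          Gn.slice(s) = img.submat(ms[s].i, ms[s].j, ms[s].i + B - 1, ms[s].j + B - 1);
        double wgt;
        if (!basic) {                       // pass 1: hard threshold
          dct3(Gn, D2, D1[g], false);
          int nret = 0;
          for (uword t = 0; t < Gn.n_elem; ++t) {
            if (t == 0 || std::abs(Gn(t)) >= lambda * sigma) ++nret;
            else Gn(t) = 0.0;
          }
          dct3(Gn, D2, D1[g], true);
          wgt = 1.0 / std::max(1, nret);
        } else {                            // pass 2: Wiener
          cube Gb(B, B, g);
          for (int s = 0; s < g; ++s)
            Gb.slice(s) = basic->submat(ms[s].i, ms[s].j,
                                        ms[s].i + B - 1, ms[s].j + B - 1);
          dct3(Gn, D2, D1[g], false);
          dct3(Gb, D2, D1[g], false);
          double wsum = 0.0;
          for (uword t = 0; t < Gn.n_elem; ++t) {
            const double b2 = Gb(t) * Gb(t);
            const double sh = b2 / (b2 + sigma * sigma);
            Gn(t) *= sh;
            wsum += sh * sh;
          }
          dct3(Gn, D2, D1[g], true);
          wgt = 1.0 / std::max(wsum, 1e-8);
        }
        for (int s = 0; s < g; ++s) {
          num.submat(ms[s].i, ms[s].j, ms[s].i + B - 1, ms[s].j + B - 1) +=
            wgt * Gn.slice(s);
          den.submat(ms[s].i, ms[s].j, ms[s].i + B - 1, ms[s].j + B - 1) += wgt;
        }
      }
    den.replace(0.0, 1.0);
    return num / den;
  };

  const mat basic = run_pass(img, nullptr);
  if (sigma <= 0) return basic;
  return run_pass(basic, &basic);
}
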