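// Multi-pool Bloch-McConnell generator and pulsed-saturation propagation.
//
// State ordering for n pools: (Mx_1..Mx_n, My_1..My_n, Mz_1..Mz_n), water
// is pool 1.  All rates in 1/s, frequencies in rad/s.  The inhomogeneous
// system dM/dt = A M + b is propagated exactly per piecewise-constant
// segment through the (3n+1)-dimensional augmented matrix exponential.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Assemble A (3n x 3n) and b (3n) for one irradiation condition.
// dw[i]  : saturation offset relative to pool i resonance (rad/s)
// f[i]   : pool size ratio relative to water (f[0] = 1 by convention)
// k[i]   : exchange rate pool i -> water (1/s), k[0] ignored
static void bm_fill(const vec& r1, const vec& r2, const vec& dw,
                    const vec& f, const vec& k, double w1,
                    mat& A, vec& b) {
  const uword n = r1.n_elem;
  A.zeros(3 * n, 3 * n);
  b.zeros(3 * n);
  for (uword i = 0; i < n; ++i) {
    const uword x = i, y = n + i, z = 2 * n + i;
    A(x, x) = -r2(i);  A(x, y) =  dw(i);
    A(y, x) = -dw(i);  A(y, y) = -r2(i);  A(y, z) = w1;
    A(z, y) = -w1;     A(z, z) = -r1(i);
    b(z) = r1(i) * (i == 0 ? 1.0 : f(i));
  }
  // exchange water <-> each solute pool, detailed balance k_w->i = f_i k_i
  for (uword i = 1; i < n; ++i) {
    const double kb = k(i), kw = f(i) * k(i);
    for (uword c = 0; c < 3; ++c) {
      const uword w = c * n, s = c * n + i;
      A(w, w) -= kw;  A(w, s) += kb;
      A(s, s) -= kb;  A(s, w) += kw;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_bm_generator(const arma::vec& r1, const arma::vec& r2,
                            const arma::vec& dw, const arma::vec& f,
                            const arma::vec& k, double w1) {
  mat A; vec b;
  bm_fill(r1, r2, dw, f, k, w1, A, b);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("b") = b);
}

// Augmented propagator exp([[A, b], [0, 0]] * dt)
static mat aug_prop(const mat& A, const vec& b, double dt) {
  const uword m = A.n_rows;
  mat G(m + 1, m + 1, fill::zeros);
  G.submat(0, 0, m - 1, m - 1) = A;
  G.col(m).head(m) = b;
  return expmat(G * dt);
}

// Z-spectrum under a train of n_pulses piecewise-constant shaped pulses
// (segment amplitudes w1_seg, each lasting dt_seg seconds) interleaved
// with free relaxation of td seconds.  delta_rad are per-pool chemical
// shifts (rad/s); offsets_rad the saturation frequencies (rad/s).
// Magnetization starts fully relaxed at every offset.
// [[Rcpp::export]]
arma::vec cpp_zspectrum(const arma::vec& r1, const arma::vec& r2,
                        const arma::vec& delta_rad, const arma::vec& f,
                        const arma::vec& k, const arma::vec& offsets_rad,
                        const arma::vec& w1_seg, double dt_seg,
                        double td_s, int n_pulses) {
  const uword n = r1.n_elem, m = 3 * n;
  vec z(offsets_rad.n_elem);
  mat A; vec b;
  vec Meq(m + 1, fill::zeros);
  Meq(2 * n) = 1.0;                       // water Mz
  for (uword i = 1; i < n; ++i) Meq(2 * n + i) = f(i);
  Meq(m) = 1.0;                           // augmentation constant
  for (uword o = 0; o < offsets_rad.n_elem; ++o) {
    const vec dw = offsets_rad(o) - delta_rad;
    // one shaped pulse = product of segment propagators
    mat P(m + 1, m + 1, fill::eye);
    for (uword s = 0; s < w1_seg.n_elem; ++s) {
      bm_fill(r1, r2, dw, f, k, w1_seg(s), A, b);
      P = aug_prop(A, b, dt_seg) * P;
    }
    if (td_s > 0) {
      bm_fill(r1, r2, dw, f, k, 0.0, A, b);
      P = aug_prop(A, b, td_s) * P;       // pulse then interpulse delay
    }
    vec M = Meq;
    for (int p = 0; p < n_pulses; ++p) M = P * M;
    z(o) = M(2 * n);                      // water Mz / M0 (M0 = 1)
  }
  return z;
}
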