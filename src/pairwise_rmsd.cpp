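// Compiled kernels for all-pairs least RMSD (determinant-corrected Kabsch).
// The per-pair work is a 3x3 cross-covariance H; its singular values are
// obtained in closed form from the eigenvalues of H^T H (trigonometric
// solution for symmetric 3x3), avoiding a LAPACK call per pair.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// eigenvalues of a symmetric 3x3, descending
static inline void sym3_eigvals(const mat33& A, double ev[3]) {
  const double p1 = A(0, 1) * A(0, 1) + A(0, 2) * A(0, 2) +
                    A(1, 2) * A(1, 2);
  const double q = (A(0, 0) + A(1, 1) + A(2, 2)) / 3.0;
  if (p1 == 0.0) {
    ev[0] = A(0, 0); ev[1] = A(1, 1); ev[2] = A(2, 2);
  } else {
    const double p2 = (A(0, 0) - q) * (A(0, 0) - q) +
                      (A(1, 1) - q) * (A(1, 1) - q) +
                      (A(2, 2) - q) * (A(2, 2) - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    mat33 B = (A - q * eye(3, 3)) / p;
    double r = det(B) / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    const double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  std::sort(ev, ev + 3, std::greater<double>());
}

static inline double kabsch_rmsd_centered(const mat& A, const mat& B,
                                          double ssA, double ssB) {
  mat33 H = A.t() * B;
  mat33 K = H.t() * H;
  double ev[3];
  sym3_eigvals(K, ev);
  const double s0 = std::sqrt(std::max(ev[0], 0.0));
  const double s1 = std::sqrt(std::max(ev[1], 0.0));
  const double s2 = std::sqrt(std::max(ev[2], 0.0));
  const double d = det(H) < 0 ? -1.0 : 1.0;
  const double msd = (ssA + ssB - 2.0 * (s0 + s1 + d * s2)) / A.n_rows;
  return msd > 0 ? std::sqrt(msd) : 0.0;
}

// coords: n_res x 3 x n cube
// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& coords) {
  const uword n = coords.n_slices;
  std::vector<mat> centered(n);
  std::vector<double> ss(n);
  for (uword i = 0; i < n; ++i) {
    mat M = coords.slice(i);
    M.each_row() -= mean(M, 0);
    centered[i] = M;
    ss[i] = accu(square(M));
  }
  mat out(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      double r = kabsch_rmsd_centered(centered[i], centered[j], ss[i], ss[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// least RMSD of every slice of `coords` against a single reference (n_res x 3)
// [[Rcpp::export]]
arma::vec rmsd_to_ref_cpp(const arma::cube& coords, const arma::mat& ref) {
  const uword n = coords.n_slices;
  mat R = ref;
  R.each_row() -= mean(R, 0);
  double ssR = accu(square(R));
  vec out(n);
  for (uword i = 0; i < n; ++i) {
    mat M = coords.slice(i);
    M.each_row() -= mean(M, 0);
    out(i) = kabsch_rmsd_centered(M, R, accu(square(M)), ssR);
  }
  return out;
}
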