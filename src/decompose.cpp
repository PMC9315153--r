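// Per-pixel Lu-Chipman polar decomposition. Mirrors the scalar R reference
// implementation lu_chipman() step for step; tests assert agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: 16 x Npix, each column a 4x4 Mueller matrix in column-major order.
// Returns 4 x Npix: rows D, delta, Delta, flag (0 = clean).
// [[Rcpp::export]]
arma::mat mmpd_pixels(const arma::mat& X) {
  const uword n = X.n_cols;
  mat out(4, n, fill::zeros);
  const double tol = 1e-9;

  for (uword p = 0; p < n; ++p) {
    mat M(const_cast<double*>(X.colptr(p)), 4, 4, false, true);
    mat N = M / M(0, 0);
    double flag = 0.0;

    vec d = N.submat(0, 1, 0, 3).t();
    double D = norm(d);
    if (D > 1.0) {
      if (D > 1.0 + 1e-6) flag = 1.0;
      d /= D;
      D = 1.0;
    }
    double a = std::sqrt(std::max(0.0, 1.0 - D * D));
    mat mD = eye(3, 3);
    if (D > 0) {
      vec dh = d / D;
      mD = a * eye(3, 3) + (1.0 - a) * (dh * dh.t());
    }
    mat MD(4, 4);
    MD(0, 0) = 1.0;
    MD.submat(0, 1, 0, 3) = d.t();
    MD.submat(1, 0, 3, 0) = d;
    MD.submat(1, 1, 3, 3) = mD;

    mat MDi;
    if (1.0 - D * D > 1e-12) {
      MDi = inv(MD);
    } else {
      MDi = pinv(MD, 1e-12);
    }
    mat Mp = N * MDi;
    mat mp = Mp.submat(1, 1, 3, 3);

    mat C = mp * mp.t();
    C = (C + C.t()) / 2.0;
    vec lam;
    mat V;
    eig_sym(lam, V, C);
    if (lam.min() < -tol) flag = 1.0;
    lam = clamp(lam, 0.0, datum::inf);
    double sdet = (det(mp) < 0) ? -1.0 : 1.0;
    vec slam = sqrt(lam);
    mat mDelta = sdet * (V * diagmat(slam) * V.t());

    mat mR;
    if (slam.min() > 1e-12 * std::max(slam.max(), 1e-12)) {
      mR = solve(mDelta, mp);
    } else {
      mR = pinv(mDelta, 1e-12) * mp;
      flag = 1.0;
    }

    double arg = std::sqrt(std::pow(mR(0, 0) + mR(1, 1), 2) +
                           std::pow(mR(1, 0) - mR(0, 1), 2)) - 1.0;
    if (std::abs(arg) > 1.0 + 1e-6) flag = 1.0;
    arg = std::min(1.0, std::max(-1.0, arg));
    double delta = std::acos(arg);

    double Delta = 1.0 - std::abs(sdet * accu(slam)) / 3.0;
    Delta = std::min(1.0, std::max(0.0, Delta));

    out(0, p) = D;
    out(1, p) = delta;
    out(2, p) = Delta;
    out(3, p) = flag;
  }
  return out;
}
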