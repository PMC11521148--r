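// Vectorized Lu-Chipman polar decomposition over per-pixel Mueller
// matrices. Input: N x 16 matrix, each row vec(M) column-major.
// Output columns: D, R_deg, delta_deg, psi_deg, Delta, DeltaL, DeltaC,
// axis_deg, b, t, A_mmt. Scalar definitions mirror the R reference
// implementation mmpdDecomposePixel(); the two are cross-checked in tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double RAD2DEG = 57.29577951308232;

static double clip_unit(double x, int &clips) {
  if (x > 1.0) { clips++; return 1.0; }
  if (x < -1.0) { clips++; return -1.0; }
  return x;
}

// [[Rcpp::export(name = ".mmpd_maps_cpp")]]
Rcpp::List mmpd_maps_cpp(const arma::mat &Mflat) {
  const arma::uword n = Mflat.n_rows;
  arma::mat out(n, 11);
  out.fill(arma::datum::nan);
  int clips = 0;

  for (arma::uword p = 0; p < n; ++p) {
    arma::mat M(4, 4);
    for (int j = 0; j < 4; ++j)
      for (int i = 0; i < 4; ++i)
        M(i, j) = Mflat(p, 4 * j + i);
    double m11 = M(0, 0);
    if (!std::isfinite(m11) || m11 <= 0.0) continue;
    M /= m11;

    // diattenuator factor
    arma::vec dv = M.row(0).subvec(1, 3).t();
    double D = arma::norm(dv);
    arma::mat Mp;             // M' = M * MD^{-1}
    if (D < 1e-12) {
      Mp = M;
      D = arma::norm(dv);
    } else {
      if (D > 1.0) { D = 1.0; clips++; }
      arma::vec dh = dv / std::max(arma::norm(dv), 1e-300);
      double sq = std::sqrt(std::max(1.0 - D * D, 0.0));
      arma::mat mD3 = sq * arma::eye(3, 3) + (1.0 - sq) * dh * dh.t();
      arma::mat MD = arma::eye(4, 4);
      MD(0, 0) = 1.0;
      MD.submat(0, 1, 0, 3) = dv.t();
      MD.submat(1, 0, 3, 0) = dv;
      MD.submat(1, 1, 3, 3) = mD3;
      arma::mat MDi;
      if (!arma::inv(MDi, MD)) MDi = arma::pinv(MD);
      Mp = M * MDi;
    }

    arma::mat mp = Mp.submat(1, 1, 3, 3);
    arma::mat S = mp * mp.t();
    arma::vec lam;
    arma::eig_sym(lam, S);              // ascending
    arma::vec s(3);
    for (int i = 0; i < 3; ++i) {
      double l = lam(2 - i);
      if (l < 0) { l = 0; clips++; }
      s(i) = std::sqrt(l);              // descending singular values
    }
    double k1 = s(0) + s(1) + s(2);
    double k2 = s(0) * s(1) + s(1) * s(2) + s(2) * s(0);
    double k3 = s(0) * s(1) * s(2);
    double sgn = (arma::det(mp) >= 0.0) ? 1.0 : -1.0;
    arma::mat mDel;
    arma::mat num = k1 * S + k3 * arma::eye(3, 3);
    arma::mat den = S + k2 * arma::eye(3, 3);
    arma::mat deni;
    if (!arma::inv(deni, den)) deni = arma::pinv(den);
    mDel = sgn * deni * num;

    arma::mat mDeli;
    if (!arma::inv(mDeli, mDel)) mDeli = arma::pinv(mDel);
    arma::mat mR = mDeli * mp;

    double trR = 1.0 + arma::trace(mR);
    double R = std::acos(clip_unit(trR / 2.0 - 1.0, clips)) * RAD2DEG;
    double a22 = mR(0, 0), a33 = mR(1, 1);
    double a32 = mR(1, 0), a23 = mR(0, 1);
    double delta = std::acos(clip_unit(
        std::sqrt((a22 + a33) * (a22 + a33) + (a32 - a23) * (a32 - a23)) - 1.0,
        clips)) * RAD2DEG;
    double psi = std::atan2(a32 - a23, a22 + a33) * RAD2DEG;
    double Delta = 1.0 - std::fabs(arma::trace(mDel)) / 3.0;
    double DeltaL = 1.0 - (std::fabs(mDel(0, 0)) + std::fabs(mDel(1, 1))) / 2.0;
    double DeltaC = 1.0 - std::fabs(mDel(2, 2));
    // fast axis from the retardance vector components
    double r1 = mR(1, 2) - mR(2, 1);
    double r2 = mR(2, 0) - mR(0, 2);
    double axis = NA_REAL;
    if (std::sqrt(r1 * r1 + r2 * r2) > 1e-9)
      axis = 0.5 * std::atan2(r2, r1) * RAD2DEG;

    // Mueller-matrix-transformation parameters on the normalized matrix
    double b = (M(1, 1) + M(2, 2)) / 2.0;
    double tt = std::sqrt(std::pow(M(1, 1) - M(2, 2), 2) +
                          std::pow(M(1, 2) + M(2, 1), 2)) / 2.0;
    double Ammt = (b == 0.0 && tt == 0.0) ? 0.0
                  : 2.0 * b * tt / (b * b + tt * tt);

    out(p, 0) = D;      out(p, 1) = R;      out(p, 2) = delta;
    out(p, 3) = psi;    out(p, 4) = Delta;  out(p, 5) = DeltaL;
    out(p, 6) = DeltaC; out(p, 7) = axis;   out(p, 8) = b;
    out(p, 9) = tt;     out(p, 10) = Ammt;
  }
  return Rcpp::List::create(Rcpp::Named("maps") = out,
                            Rcpp::Named("clips") = clips);
}
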