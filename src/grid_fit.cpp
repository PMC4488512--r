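// Exhaustive (r, p) grid search for the helical curve best fitting one
// quadruple of consecutive C-alpha atoms.  For each grid cell the turn
// angle t follows from the chord identity with the mean consecutive
// distance, the canonical curve points at u = 0..3 are superposed onto the
// quadruple by Kabsch/SVD (reflections excluded), and the cell with the
// smallest index-paired RMSD wins (strict improvement, so ties resolve to
// the first-encountered cell in ascending r-then-p scan order).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_fit_grid(const arma::mat& quad, const arma::vec& r_grid,
                        const arma::vec& p_grid, const double dbar) {
  if (quad.n_rows != 4 || quad.n_cols != 3)
    Rcpp::stop("quad must be 4x3");
  const rowvec ct = mean(quad, 0);
  mat b = quad;
  b.each_row() -= ct;
  const double bb = accu(b % b);

  double best = datum::inf;
  double best_r = NA_REAL, best_p = NA_REAL, best_t = NA_REAL;
  mat best_rot(3, 3, fill::eye);
  vec best_trans(3, fill::zeros);
  bool found = false;

  mat m(4, 3), a(4, 3), h(3, 3), u(3, 3), v(3, 3), rot(3, 3);
  vec s(3);

  for (uword ir = 0; ir < r_grid.n_elem; ++ir) {
    const double r = r_grid(ir);
    if (r <= 0) continue;
    for (uword ip = 0; ip < p_grid.n_elem; ++ip) {
      const double p = p_grid(ip);
      if (p < 0 || dbar <= p) continue;
      const double arg = 0.5 * std::sqrt(dbar * dbar - p * p) / r;
      if (arg > 1.0) continue;
      const double t = 2.0 * std::asin(arg);  // radians
      for (int k = 0; k < 4; ++k) {
        m(k, 0) = r * std::sin(k * t);
        m(k, 1) = r * std::cos(k * t);
        m(k, 2) = k * p;
      }
      const rowvec cm = mean(m, 0);
      a = m;
      a.each_row() -= cm;
      h = a.t() * b;
      if (!svd(u, s, v, h)) continue;
      const double d = det(v * u.t()) < 0 ? -1.0 : 1.0;
      const double tr = s(0) + s(1) + d * s(2);
      double e2 = accu(a % a) + bb - 2.0 * tr;
      if (e2 < 0) e2 = 0;
      const double rmsd = std::sqrt(e2 / 4.0);
      if (rmsd < best) {
        best = rmsd;
        best_r = r; best_p = p; best_t = t * 180.0 / datum::pi;
        vec s3 = {1.0, 1.0, d};
        rot = v * diagmat(s3) * u.t();
        best_rot = rot;
        best_trans = ct.t() - rot * cm.t();
        found = true;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("valid") = found,
      Rcpp::Named("r") = best_r, Rcpp::Named("p") = best_p,
      Rcpp::Named("t") = best_t, Rcpp::Named("rmsd_paired") = best,
      Rcpp::Named("rotation") = best_rot,
      Rcpp::Named("translation") = best_trans);
}
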