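#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batched local quadric terrain model.
//
// For each query point, fit z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2
// by least squares to its k nearest terrain points (nn_idx, 1-based) and
// evaluate the surface at the query (x, y). Coordinates are centered on the
// query for conditioning. Falls back to a plane fit (and, failing that, the
// mean neighbor z) when the local system is rank-deficient; fallbacks are
// flagged.
// [[Rcpp::export]]
List quadric_surface_z(const arma::mat& query, const arma::mat& terrain,
                       const arma::imat& nn_idx) {
  const arma::uword n = query.n_rows;
  const arma::uword k = nn_idx.n_cols;
  arma::vec zhat(n);
  LogicalVector flagged(n);

  arma::mat A(k, 6);
  arma::vec b(k);
  for (arma::uword i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1);
    arma::uword kk = 0;
    for (arma::uword j = 0; j < k; ++j) {
      const arma::sword id = nn_idx(i, j) - 1;
      if (id < 0) continue;
      const double x = terrain(id, 0) - qx;
      const double y = terrain(id, 1) - qy;
      A(kk, 0) = 1.0; A(kk, 1) = x; A(kk, 2) = y;
      A(kk, 3) = x * x; A(kk, 4) = x * y; A(kk, 5) = y * y;
      b(kk) = terrain(id, 2);
      ++kk;
    }
    bool ok = false;
    if (kk >= 6) {
      arma::vec coef;
      ok = arma::solve(coef, A.rows(0, kk - 1), b.subvec(0, kk - 1),
                       arma::solve_opts::no_approx);
      if (ok && coef.is_finite()) {
        zhat(i) = coef(0);  // evaluated at centered (0, 0)
      } else ok = false;
    }
    if (!ok && kk >= 3) {   // plane fallback
      arma::vec coef;
      bool pok = arma::solve(coef, A.submat(0, 0, kk - 1, 2),
                             b.subvec(0, kk - 1), arma::solve_opts::no_approx);
      if (pok && coef.is_finite()) {
        zhat(i) = coef(0);
        flagged(i) = true;
        ok = true;
      }
    }
    if (!ok) {              // mean-z fallback
      zhat(i) = kk > 0 ? arma::mean(b.subvec(0, kk - 1)) : NA_REAL;
      flagged(i) = true;
    }
  }
  return List::create(_["z"] = zhat, _["flagged"] = flagged);
}
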