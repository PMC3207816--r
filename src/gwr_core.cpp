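#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One weighted least-squares fit per focal cell.
//
// X        n x k design matrix (first column the intercept)
// y        n response
// D        n x n great-circle distance matrix (km)
// bandwidth  kernel bandwidth b (km)
// kernel   0 = bi-square (1 - (d/b)^2)^2 for d < b; 1 = moving window, d <= b
// cond_tol   reciprocal-condition threshold on the weighted design:
//            singular-value ratio above 1/cond_tol marks the fit unreliable
//
// Solves via thin SVD of sqrt(w)-scaled design (rank-revealing; singular
// values below 1e-10 of the largest are truncated).  Returns per-cell
// coefficients, weighted local R^2, focal residual y_i - x_i' beta_i,
// hat diagonal s_ii = x_i' (X'WX)^- x_i * w_i, positive-weight count and
// a reliability flag.  Unreliable cells keep their (pseudo-inverse)
// residual and leverage so the global fit statistics remain defined, but
// coefficients and local R^2 are reported as NA.
// [[Rcpp::export]]
List gwr_local_fits(const arma::mat& X, const arma::vec& y,
                    const arma::mat& D, const double bandwidth,
                    const int kernel, const double cond_tol) {
  const arma::uword n = X.n_rows;
  const arma::uword k = X.n_cols;
  const double sv_tol = 1e-10;

  arma::mat beta(n, k);
  beta.fill(arma::datum::nan);
  arma::vec r2(n);  r2.fill(arma::datum::nan);
  arma::vec s_ii(n, arma::fill::zeros);
  arma::vec resid(n, arma::fill::zeros);
  arma::ivec n_nonzero(n, arma::fill::zeros);
  arma::ivec reliable(n, arma::fill::zeros);

  for (arma::uword i = 0; i < n; ++i) {
    arma::vec w(n, arma::fill::zeros);
    if (kernel == 0) {
      for (arma::uword j = 0; j < n; ++j) {
        const double d = D(j, i);
        if (d < bandwidth) {
          const double u = 1.0 - (d / bandwidth) * (d / bandwidth);
          w(j) = u * u;
        }
      }
    } else {
      for (arma::uword j = 0; j < n; ++j) {
        if (D(j, i) <= bandwidth) w(j) = 1.0;
      }
    }

    const arma::uvec pos = arma::find(w > 0.0);
    n_nonzero(i) = static_cast<int>(pos.n_elem);

    const arma::vec sw = arma::sqrt(w);
    arma::mat Xs = X.each_col() % sw;
    const arma::vec ys = y % sw;

    arma::mat U, V;
    arma::vec s;
    const bool ok = arma::svd_econ(U, s, V, Xs);
    if (!ok || s.n_elem < k || s(0) <= 0.0) continue;

    const double cond = s(0) / std::max(s(k - 1), 0.0);
    arma::vec s_inv(k, arma::fill::zeros);
    for (arma::uword m = 0; m < k; ++m) {
      if (s(m) > sv_tol * s(0)) s_inv(m) = 1.0 / s(m);
    }

    const arma::vec b = V * (s_inv % (U.t() * ys));
    const arma::vec fitted = X * b;

    // weighted fit statistics around the weighted mean
    const double sw_sum = arma::accu(w);
    const double ybar_w = arma::dot(w, y) / sw_sum;
    const double rss = arma::dot(w, arma::square(y - fitted));
    const double tss = arma::dot(w, arma::square(y - ybar_w));

    resid(i) = y(i) - fitted(i);
    const arma::vec v = V.t() * X.row(i).t();
    s_ii(i) = arma::accu(arma::square(v % s_inv)) * w(i);

    const bool rel = (pos.n_elem >= k + 1) &&
                     std::isfinite(cond) && (cond <= cond_tol);
    reliable(i) = rel ? 1 : 0;
    if (rel) {
      beta.row(i) = b.t();
      r2(i) = (tss > 0.0) ? 1.0 - rss / tss : arma::datum::nan;
    }
  }

  return List::create(
    Named("beta") = beta,
    Named("local_r2") = r2,
    Named("s_ii") = s_ii,
    Named("resid") = resid,
    Named("n_nonzero") = n_nonzero,
    Named("reliable") = reliable);
}
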