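// Leave-one-out RMSECV for PLS1 via the crossproduct (kernel) formulation:
// X'X and X'y are computed once and downdated per held-out sample, so each
// refit costs O(p^2 * ncomp) instead of O(n * p * ncomp).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Coefficient path B(:, k-1) for k components from centered crossproducts.
// Mirrors the R reference implementation (pls_coef_path) exactly.
static void pls_coef_path_arma(const mat& S, const vec& s, const int ncomp,
                               mat& B) {
  const uword p = s.n_elem;
  B.zeros(p, ncomp);
  mat Rm(p, ncomp, fill::zeros), Pm(p, ncomp, fill::zeros);
  vec b(p, fill::zeros);
  vec a = s;
  const vec s0 = s;
  const double scale0 = dot(s0, s0);
  if (scale0 < DBL_MIN) return;
  const double strace = trace(S);
  for (int h = 0; h < ncomp; ++h) {
    const double nw2 = dot(a, a);
    if (nw2 <= 1e-24 * scale0) {
      for (int j = h; j < ncomp; ++j) B.col(j) = b;
      return;
    }
    vec w = a / std::sqrt(nw2);
    vec r = w;
    if (h > 0) {
      r -= Rm.cols(0, h - 1) * (Pm.cols(0, h - 1).t() * w);
    }
    const vec Sr = S * r;
    const double tt = dot(r, Sr);
    if (!std::isfinite(tt) || tt <= 1e-24 * strace) {
      for (int j = h; j < ncomp; ++j) B.col(j) = b;
      return;
    }
    Rm.col(h) = r;
    Pm.col(h) = Sr / tt;
    const double q = dot(r, s0) / tt;
    b += q * r;
    B.col(h) = b;
    a -= Pm.col(h) * (q * tt);
  }
}

// [[Rcpp::export(name = ".loo_rmsecv_cpp")]]
arma::vec loo_rmsecv_cpp(const arma::mat& X, const arma::vec& y,
                         const int max_ncomp) {
  const uword n = X.n_rows;
  const uword p = X.n_cols;
  const mat Sxx = X.t() * X;
  const vec sxy = X.t() * y;
  const vec sx = sum(X, 0).t();
  const double sy = accu(y);
  vec sqerr(max_ncomp + 1, fill::zeros);
  mat B(p, max_ncomp);
  for (uword i = 0; i < n; ++i) {
    const vec xi = X.row(i).t();
    const double yi = y(i);
    const vec sx_i = sx - xi;
    const double sy_i = sy - yi;
    const double m = static_cast<double>(n - 1);
    const vec mx = sx_i / m;
    const double my = sy_i / m;
    const mat S = Sxx - xi * xi.t() - (sx_i * sx_i.t()) / m;
    const vec s = sxy - xi * yi - sx_i * (sy_i / m);
    pls_coef_path_arma(S, s, max_ncomp, B);
    const vec xc = xi - mx;
    const double e0 = yi - my;
    sqerr(0) += e0 * e0;
    const rowvec pred = my + xc.t() * B;
    for (int k = 0; k < max_ncomp; ++k) {
      const double e = yi - pred(k);
      sqerr(k + 1) += e * e;
    }
  }
  return sqrt(sqerr / static_cast<double>(n));
}
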