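// Profile residual-sum-of-squares for continuous piecewise-linear
// (broken-stick) regression. The model is
//   y = b0 + b1 * x + sum_j d_j * (x - psi_j)_+
// For fixed breakpoints psi the model is linear, so the profile RSS over a
// grid of psi is an exhaustive sequence of small least-squares solves; this
// is the only computational hot spot in the package and is done here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec hinge(const vec& x, const double psi) {
  vec h = x - psi;
  h.elem(find(h < 0.0)).zeros();
  return h;
}

static double rss_solve(const mat& X, const vec& y) {
  vec beta;
  const bool ok = solve(beta, X, y, solve_opts::no_approx);
  if (!ok) {
    // rank deficiency (e.g. a breakpoint beyond the data range): use the
    // minimum-norm least-squares solution instead.
    beta = pinv(X) * y;
  }
  const vec r = y - X * beta;
  return dot(r, r);
}

// [[Rcpp::export]]
arma::vec rss_profile_1bp(const arma::vec& x, const arma::vec& y,
                          const arma::vec& psi_grid) {
  const uword n = x.n_elem, m = psi_grid.n_elem;
  mat X(n, 3);
  X.col(0).ones();
  X.col(1) = x;
  vec out(m);
  for (uword i = 0; i < m; ++i) {
    X.col(2) = hinge(x, psi_grid[i]);
    out[i] = rss_solve(X, y);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat rss_profile_2bp(const arma::vec& x, const arma::vec& y,
                          const arma::vec& psi1_grid,
                          const arma::vec& psi2_grid) {
  const uword n = x.n_elem;
  const uword m1 = psi1_grid.n_elem, m2 = psi2_grid.n_elem;
  mat X(n, 4);
  X.col(0).ones();
  X.col(1) = x;
  mat out(m1, m2);
  out.fill(datum::inf);
  for (uword i = 0; i < m1; ++i) {
    X.col(2) = hinge(x, psi1_grid[i]);
    for (uword j = 0; j < m2; ++j) {
      if (psi2_grid[j] - psi1_grid[i] < 1e-9) continue;  // enforce psi1 < psi2
      X.col(3) = hinge(x, psi2_grid[j]);
      out(i, j) = rss_solve(X, y);
    }
  }
  return out;
}

// [[Rcpp::export]]
double rss_at_psi(const arma::vec& x, const arma::vec& y,
                  const arma::vec& psi) {
  const uword n = x.n_elem, p = psi.n_elem;
  mat X(n, 2 + p);
  X.col(0).ones();
  X.col(1) = x;
  for (uword j = 0; j < p; ++j) X.col(2 + j) = hinge(x, psi[j]);
  return rss_solve(X, y);
}
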