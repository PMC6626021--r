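// Alternating constrained least squares core for reference-free cell-type
// deconvolution: Y (CpG x sample) ~ M Omega^T with M in [0,1] elementwise
// and Omega rows on the probability simplex.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact minimizer of ||y - M w||^2 s.t. w >= 0, sum(w) = 1, by an
// active-set method on the KKT system. A = M'M, b = M'y.
static vec simplex_ls_one(const mat& A, const vec& b) {
  const uword n = b.n_elem;
  if (n == 1) return vec(1, fill::ones);
  uvec is_free(n, fill::ones);
  vec w(n, fill::zeros);
  const int max_pass = 4 * static_cast<int>(n) + 8;
  for (int pass = 0; pass < max_pass; ++pass) {
    uvec F = find(is_free == 1);
    mat AF = A.submat(F, F);
    vec bF = b.elem(F);
    mat R;
    if (!chol(R, AF)) {
      AF.diag() += 1e-10 * std::max(AF.diag().max(), 1.0);
      if (!chol(R, AF)) Rcpp::stop("Cholesky failure in simplex solver");
    }
    vec Ainv_b = solve(trimatu(R), solve(trimatl(R.t()), bF));
    vec Ainv_1 = solve(trimatu(R), solve(trimatl(R.t()),
                                         vec(F.n_elem, fill::ones)));
    double lambda = (accu(Ainv_b) - 1.0) / accu(Ainv_1);
    vec wF = Ainv_b - lambda * Ainv_1;
    if (wF.min() < -1e-10) {
      is_free(F(wF.index_min())) = 0;
      if (accu(is_free) == 0) {            // numerically degenerate
        vec crit = b - 0.5 * A.diag();
        is_free(crit.index_max()) = 1;
      }
      continue;
    }
    w.zeros();
    w.elem(F) = clamp(wF, 0.0, datum::inf);
    // KKT: zeroed coordinates need nonnegative reduced gradient
    vec grad = A * w - b + lambda;
    double worst = -1e-8;
    sword worst_i = -1;
    for (uword i = 0; i < n; ++i)
      if (is_free(i) == 0 && grad(i) < worst) { worst = grad(i); worst_i = i; }
    if (worst_i < 0) break;
    is_free(worst_i) = 1;
  }
  return w;
}

// Mixture rows for all samples of Y holding M fixed: the sum-to-one
// equality-constrained solution in one shot, active-set fallback for
// samples leaving the simplex.
// [[Rcpp::export]]
arma::mat omega_update_cpp(const arma::mat& Y, const arma::mat& M) {
  const uword T = M.n_cols, n = Y.n_cols;
  if (T == 1) return mat(n, 1, fill::ones);
  mat A = M.t() * M;
  mat B = M.t() * Y;
  mat R;
  if (!chol(R, A)) {
    mat A2 = A;
    A2.diag() += 1e-10 * std::max(A.diag().max(), 1.0);
    if (!chol(R, A2)) Rcpp::stop("Cholesky failure in mixture update");
    A = A2;
  }
  mat W = solve(trimatu(R), solve(trimatl(R.t()), B));
  vec u = solve(trimatu(R), solve(trimatl(R.t()), vec(T, fill::ones)));
  rowvec lam = (sum(W, 0) - 1.0) / accu(u);
  W -= u * lam;
  for (uword j = 0; j < n; ++j)
    if (W.col(j).min() < -1e-10) W.col(j) = simplex_ls_one(A, B.col(j));
  W = clamp(W, 0.0, datum::inf);
  return W.t();
}

// Box-constrained profile update by exact cyclic coordinate descent,
// vectorized over CpGs; each coordinate update is an exact clipped
// minimization, so the objective never increases.
static void m_update(const mat& Y, mat& M, const mat& Omega,
                     int sweeps, double tol) {
  mat G = Omega.t() * Omega;
  mat B = Y * Omega;
  const uword T = M.n_cols;
  for (int s = 0; s < sweeps; ++s) {
    double delta = 0.0;
    for (uword t = 0; t < T; ++t) {
      if (G(t, t) <= 0) continue;
      vec mt = (B.col(t) - M * G.col(t) + M.col(t) * G(t, t)) / G(t, t);
      mt = clamp(mt, 0.0, 1.0);
      delta = std::max(delta, abs(mt - M.col(t)).max());
      M.col(t) = mt;
    }
    if (delta < tol) break;
  }
}

// Full alternating fit from starting profiles M0; returns M, Omega and the
// per-iteration RSS trajectory.
// [[Rcpp::export]]
Rcpp::List als_fit_cpp(const arma::mat& Y, arma::mat M,
                       int max_iter, double tol) {
  std::vector<double> traj;
  traj.reserve(max_iter);
  double prev = datum::inf;
  bool converged = false;
  mat Omega;
  for (int it = 0; it < max_iter; ++it) {
    Omega = omega_update_cpp(Y, M);
    m_update(Y, M, Omega, 8, 1e-9);
    double rss = accu(square(Y - M * Omega.t()));
    traj.push_back(rss);
    if (std::isfinite(prev) && (prev - rss) <= tol * std::max(prev, 1e-12)) {
      converged = true;
      break;
    }
    prev = rss;
  }
  return Rcpp::List::create(Rcpp::Named("M") = M,
                            Rcpp::Named("Omega") = Omega,
                            Rcpp::Named("trajectory") = traj,
                            Rcpp::Named("converged") = converged);
}
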