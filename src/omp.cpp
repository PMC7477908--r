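// Orthogonal matching pursuit over the columns of a signal matrix.
// Greedy atom selection by maximal |<residual, atom>| (conjugated on the
// atom side), with a full least-squares refit on the selected support after
// every selection. Ties break to the lowest atom index; iteration stops at
// T0 atoms or when the residual 2-norm drops to `tol`.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".omp_batch_cx")]]
arma::cx_mat omp_batch_cx(const arma::cx_mat& D, const arma::cx_mat& Y,
                          const int T0, const double tol) {
  const uword m = D.n_rows, n = D.n_cols, N = Y.n_cols;
  if (Y.n_rows != m) Rcpp::stop("signal dimension does not match dictionary");
  if (T0 < 1) Rcpp::stop("T0 must be >= 1");
  const vec anorm = sqrt(sum(square(abs(D)), 0)).t();
  if (anorm.min() < 1e-12) Rcpp::stop("dictionary contains a zero-norm atom");

  cx_mat X(n, N, fill::zeros);
  const int cap = std::min<int>(T0, (int)m);

  for (uword k = 0; k < N; ++k) {
    cx_vec y = Y.col(k);
    cx_vec r = y;
    std::vector<uword> support;
    support.reserve(cap);
    std::vector<bool> used(n, false);
    cx_vec coef;
    for (int t = 0; t < cap; ++t) {
      if (norm(r, 2) <= tol) break;
      // correlations with conjugation on the atom side
      cx_vec c = D.t() * r;  // .t() is the conjugate transpose
      double best = -1.0;
      sword pick = -1;
      for (uword j = 0; j < n; ++j) {
        if (used[j]) continue;
        const double a = std::abs(c(j));
        if (a > best + 1e-14) { best = a; pick = (sword)j; }
      }
      if (pick < 0 || best < 1e-13) break;
      used[(uword)pick] = true;
      support.push_back((uword)pick);
      const uvec S(support);
      coef = solve(D.cols(S), y);
      r = y - D.cols(S) * coef;
    }
    if (!support.empty()) {
      const uvec S(support);
      X(S, uvec{k}) = coef;
    }
  }
  return X;
}
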