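#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_divergence(const mat& M, const mat& R) {
  // generalized KL: sum M*log(M/R) - M + R, with 0*log0 := 0
  double obj = 0.0;
  for (uword j = 0; j < M.n_cols; ++j) {
    for (uword i = 0; i < M.n_rows; ++i) {
      double m = M(i, j), r = R(i, j);
      if (m > 0.0) obj += m * std::log(m / r) - m + r;
      else obj += r;
    }
  }
  return obj;
}

// Multiplicative-update NMF minimizing generalized Kullback-Leibler
// divergence D(M || S A). Stops when the relative objective change over a
// checkpoint interval falls below `tol` after `min_iter` iterations, or at
// `max_iter`. The objective is non-increasing under these updates.
// [[Rcpp::export]]
Rcpp::List nmf_kl_engine(const arma::mat& M, const arma::mat& S0,
                         const arma::mat& A0, const int min_iter,
                         const int max_iter, const double tol,
                         const int check_every) {
  const double eps = 1e-12;
  mat S = S0, A = A0;
  double prev = datum::inf, obj = datum::inf;
  int iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    // A update: A <- A .* (S' (M ./ SA)) ./ (S' 1)
    mat R = S * A;
    R.for_each([&](double& v) { if (v < eps) v = eps; });
    mat Q = M / R;
    vec scol = sum(S, 0).t();
    scol.for_each([&](double& v) { if (v < eps) v = eps; });
    A %= (S.t() * Q);
    A.each_col() /= scol;
    // S update: S <- S .* ((M ./ SA) A') ./ (1 A')
    R = S * A;
    R.for_each([&](double& v) { if (v < eps) v = eps; });
    Q = M / R;
    rowvec arow = sum(A, 1).t();
    arow.for_each([&](double& v) { if (v < eps) v = eps; });
    S %= (Q * A.t());
    S.each_row() /= arow;
    if (it % check_every == 0 || it == max_iter) {
      mat Rc = S * A;
      Rc.for_each([&](double& v) { if (v < eps) v = eps; });
      obj = kl_divergence(M, Rc);
      double rel = std::abs(prev - obj) / std::max(std::abs(prev), eps);
      if (it >= min_iter && std::isfinite(prev) && rel < tol) break;
      prev = obj;
    }
  }
  // absorb column scale of S into A
  rowvec cs = sum(S, 0);
  for (uword j = 0; j < S.n_cols; ++j) {
    double c = cs(j);
    if (c > 0) { S.col(j) /= c; A.row(j) *= c; }
  }
  mat Rf = S * A;
  Rf.for_each([&](double& v) { if (v < eps) v = eps; });
  obj = kl_divergence(M, Rf);
  return Rcpp::List::create(Rcpp::Named("S") = S, Rcpp::Named("A") = A,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = iters);
}
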