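// Hierarchical alternating least squares (HALS) for unregularized NMF
// minimizing the Frobenius reconstruction error ||A - W H||_F.
// Convergence: relative change of the relative error below `tol`, or
// `max_iter` sweeps. Initial W, H are supplied by the caller (seeded in R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nmf_hals(const arma::mat& A, arma::mat W, arma::mat H,
                    int max_iter, double tol) {
  const double eps = 1e-12;
  const uword k = W.n_cols;
  const double a_norm = norm(A, "fro");
  double prev = datum::inf;
  double rel_err = datum::inf;
  int iters = 0;

  for (int it = 0; it < max_iter; ++it) {
    // update W given H
    mat HHt = H * H.t();            // k x k
    mat AHt = A * H.t();            // g x k
    for (uword j = 0; j < k; ++j) {
      double denom = HHt(j, j);
      if (denom < eps) denom = eps;
      vec wj = W.col(j) + (AHt.col(j) - W * HHt.col(j)) / denom;
      wj.transform([](double v) { return v > 0.0 ? v : 0.0; });
      if (accu(wj) < eps) wj.fill(eps);  // avoid dead factors
      W.col(j) = wj;
    }
    // update H given W
    mat WtW = W.t() * W;            // k x k
    mat WtA = W.t() * A;            // k x n
    for (uword j = 0; j < k; ++j) {
      double denom = WtW(j, j);
      if (denom < eps) denom = eps;
      rowvec hj = H.row(j) + (WtA.row(j) - WtW.row(j) * H) / denom;
      hj.transform([](double v) { return v > 0.0 ? v : 0.0; });
      H.row(j) = hj;
    }
    rel_err = norm(A - W * H, "fro") / (a_norm > 0 ? a_norm : 1.0);
    iters = it + 1;
    if (std::isfinite(prev) && prev > 0 &&
        std::fabs(prev - rel_err) / prev < tol) break;
    prev = rel_err;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("rel_error") = rel_err,
                            Rcpp::Named("iterations") = iters);
}
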