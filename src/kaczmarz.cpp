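// Regularized Kaczmarz solver for frequency-space MPI reconstruction.
//
// Solves argmin_c ||S c - u||_2^2 + lambda ||c||_2^2 (augmented-variable row
// iteration; with l1 > 0 and/or nonneg, an iterative-shrinkage hybrid applies
// soft-thresholding and a nonnegativity projection between sweeps, after
// which the iterate is real).
//
// S is passed transposed (N x M, one *column* per matrix row) so row access
// is contiguous in memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List kaczmarz_core(const arma::cx_mat& St, const arma::cx_vec& u, double lambda,
                         int sweeps, const arma::ivec& order, double l1,
                         bool nonneg) {
  const uword N = St.n_rows, M = St.n_cols;
  if (u.n_elem != M) Rcpp::stop("row/measurement size mismatch");
  cx_vec x(N, fill::zeros);
  cx_vec v(M, fill::zeros);          // auxiliary residual (Tikhonov coupling)
  vec energy(M);
  for (uword i = 0; i < M; ++i) energy(i) = std::real(cdot(St.col(i), St.col(i)));
  const double sql = std::sqrt(lambda);

  for (int s = 0; s < sweeps; ++s) {
    for (uword oi = 0; oi < M; ++oi) {
      const uword i = static_cast<uword>(order(oi));
      const double denom = energy(i) + lambda;
      if (denom <= 0) continue;
      const std::complex<double> resid =
        u(i) - dot(St.col(i), x) - sql * v(i);
      const std::complex<double> alpha = resid / denom;
      x += alpha * conj(St.col(i));
      v(i) += alpha * sql;
    }
    if (l1 > 0 || nonneg) {
      vec xr = real(x);
      if (l1 > 0) xr = sign(xr) % clamp(abs(xr) - l1, 0.0, datum::inf);
      if (nonneg) xr = clamp(xr, 0.0, datum::inf);
      x = cx_vec(xr, vec(N, fill::zeros));
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("v") = v);
}
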