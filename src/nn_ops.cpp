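// Compiled kernels for the 1D convolutional network.  Activations are laid
// out as (channels x L*B) matrices with each sample occupying a contiguous
// block of L columns.  Convolutions use implicit zero padding, evaluated as
// one small GEMM per kernel tap and sample block over column subviews (no
// padded or unrolled copies are materialized; cheapest on a single core).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::cube& W,
                         const arma::vec& b, int L, int B) {
  const int k = W.n_slices, p = (k - 1) / 2;
  mat Y(W.n_rows, X.n_cols, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int o = j - p;
    const int l0 = std::max(0, -o), l1 = L - 1 - std::max(0, o);
    if (l1 < l0) continue;
    const mat Wj = W.slice(j);
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      Y.cols(base + l0, base + l1) += Wj * X.cols(base + l0 + o, base + l1 + o);
    }
  }
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dY, const arma::cube& W,
                          const arma::mat& X, int L, int B, bool need_dx) {
  const int k = W.n_slices, p = (k - 1) / 2;
  cube dW(W.n_rows, W.n_cols, k, fill::zeros);
  vec db = sum(dY, 1);
  mat dX;
  if (need_dx) dX.zeros(X.n_rows, X.n_cols);
  for (int j = 0; j < k; ++j) {
    const int o = j - p;
    const int l0 = std::max(0, -o), l1 = L - 1 - std::max(0, o);
    if (l1 < l0) continue;
    const mat Wj = W.slice(j);
    mat& dWj = dW.slice(j);
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      const mat dYs = dY.cols(base + l0, base + l1);
      dWj += dYs * X.cols(base + l0 + o, base + l1 + o).t();
      if (need_dx)
        dX.cols(base + l0 + o, base + l1 + o) += Wj.t() * dYs;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// tanh-approximation GELU, value and elementwise derivative in one pass
// [[Rcpp::export]]
Rcpp::List gelu_cpp(const arma::mat& X) {
  mat Y(X.n_rows, X.n_cols), D(X.n_rows, X.n_cols);
  const double c0 = 0.7978845608028654;  // sqrt(2/pi)
  const double c1 = 0.044715;
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double x = X[i], x2 = x * x;
    const double u = std::tanh(c0 * x * (1.0 + c1 * x2));
    Y[i] = 0.5 * x * (1.0 + u);
    D[i] = 0.5 * (1.0 + u) + 0.5 * x * (1.0 - u * u) * c0 * (1.0 + 3.0 * c1 * x2);
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("d") = D);
}

// batch-norm statistics: per-row mean and biased variance in one pass
// [[Rcpp::export]]
Rcpp::List row_stats_cpp(const arma::mat& X) {
  const uword C = X.n_rows, N = X.n_cols;
  vec mu(C, fill::zeros), m2(C, fill::zeros);
  for (uword j = 0; j < N; ++j)
    for (uword i = 0; i < C; ++i) {
      const double v = X.at(i, j);
      mu[i] += v; m2[i] += v * v;
    }
  mu /= (double)N; m2 /= (double)N;
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = m2 - mu % mu);
}
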