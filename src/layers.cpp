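// Hot layer primitives for the dual-input convolutional model.
// Orchestration, parameter updates and the optimizer live in R (nn.R);
// these kernels only move the per-batch tensor work out of the R heap.
//
// Layout contract (must match nn.R): a batch of feature maps is an
// n x (H*W*C) matrix, entry (h, w, c) at column h + (w-1)*H + (c-1)*H*W.
// Index arguments arrive 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col gather + matmul. idx is P x K, 0-based input columns.
// [[Rcpp::export]]
List cpp_conv_forward(const arma::mat& X, const arma::mat& W,
                      const arma::vec& b, const arma::umat& idx) {
  const arma::uword n = X.n_rows, P = idx.n_rows, K = idx.n_cols,
                    F = W.n_cols;
  arma::mat cols(n * P, K);
  for (arma::uword k = 0; k < K; ++k) {
    double* dst = cols.colptr(k);
    for (arma::uword p = 0; p < P; ++p) {
      const double* src = X.colptr(idx(p, k));
      std::copy(src, src + n, dst + p * n);
    }
  }
  arma::mat Y = cols * W;
  Y.each_row() += b.t();
  Y.reshape(n, P * F);
  return List::create(_["out"] = Y, _["cols"] = cols);
}

// [[Rcpp::export]]
List cpp_conv_backward(arma::mat dY, const arma::mat& cols,
                       const arma::mat& W, const arma::umat& idx,
                       int in_size) {
  const arma::uword P = idx.n_rows, K = idx.n_cols, F = W.n_cols;
  const arma::uword n = dY.n_elem / (P * F);
  dY.reshape(n * P, F);
  arma::mat dW = cols.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * W.t();  // (n*P) x K
  arma::mat dX(n, (arma::uword)in_size, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k) {
    const double* src = dM.colptr(k);
    for (arma::uword p = 0; p < P; ++p) {
      double* dst = dX.colptr(idx(p, k));
      const double* s = src + p * n;
      for (arma::uword i = 0; i < n; ++i) dst[i] += s[i];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 stride-1 max pooling; idx4 is (P_out*C) x 4, the four candidate
// input columns per output column. Ties keep the earliest window cell.
// [[Rcpp::export]]
List cpp_pool_forward(const arma::mat& X, const arma::umat& idx4) {
  const arma::uword n = X.n_rows, PC = idx4.n_rows;
  arma::mat best(n, PC);
  arma::imat arg(n, PC);
  for (arma::uword c = 0; c < PC; ++c) {
    double* bc = best.colptr(c);
    int* ac = arg.colptr(c);
    const double* x0 = X.colptr(idx4(c, 0));
    std::copy(x0, x0 + n, bc);
    std::fill(ac, ac + n, 1);
    for (int j = 1; j < 4; ++j) {
      const double* xj = X.colptr(idx4(c, j));
      for (arma::uword i = 0; i < n; ++i) {
        if (xj[i] > bc[i]) { bc[i] = xj[i]; ac[i] = j + 1; }
      }
    }
  }
  return List::create(_["out"] = best, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::mat cpp_pool_backward(const arma::mat& dY, const arma::imat& arg,
                            const arma::umat& idx4, int in_size) {
  const arma::uword n = dY.n_rows, PC = idx4.n_rows;
  arma::mat dX(n, (arma::uword)in_size, arma::fill::zeros);
  for (arma::uword c = 0; c < PC; ++c) {
    const double* g = dY.colptr(c);
    const int* ac = arg.colptr(c);
    for (arma::uword i = 0; i < n; ++i) {
      dX(i, idx4(c, ac[i] - 1)) += g[i];
    }
  }
  return dX;
}

// Spatial batch norm: X viewed as (n*P) x C, statistics per channel.
// [[Rcpp::export]]
List cpp_bn_forward(arma::mat X, const arma::vec& gamma, const arma::vec& beta,
                    const arma::vec& run_mean, const arma::vec& run_var,
                    bool training, double eps, double momentum) {
  const arma::uword n = X.n_rows, C = gamma.n_elem;
  const arma::uword m = X.n_elem / C;
  X.reshape(m, C);
  arma::rowvec mu, v;
  if (training) {
    mu = arma::mean(X, 0);
    X.each_row() -= mu;
    v = arma::mean(arma::square(X), 0);
  } else {
    mu = run_mean.t();
    v = run_var.t();
    X.each_row() -= mu;
  }
  arma::rowvec inv = 1.0 / arma::sqrt(v + eps);
  X.each_row() %= inv;  // X is now xhat
  arma::mat Y = X;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  Y.reshape(n, m * C / n);
  if (!training) return List::create(_["out"] = Y);
  return List::create(
      _["out"] = Y, _["xhat"] = X, _["inv"] = inv,
      _["new_mean"] = momentum * run_mean + (1.0 - momentum) * mu.t(),
      _["new_var"] = momentum * run_var + (1.0 - momentum) * v.t());
}

// [[Rcpp::export]]
List cpp_bn_backward(arma::mat dY, const arma::mat& xhat,
                     const arma::rowvec& inv, const arma::vec& gamma) {
  const arma::uword n = dY.n_rows, C = gamma.n_elem;
  const arma::uword m = xhat.n_rows;
  dY.reshape(m, C);
  arma::rowvec dgamma = arma::sum(dY % xhat, 0);
  arma::rowvec dbeta = arma::sum(dY, 0);
  dY.each_row() %= gamma.t();  // dY is now d(xhat)
  arma::rowvec mean_dxhat = arma::mean(dY, 0);
  arma::rowvec mean_dxhat_xhat = arma::mean(dY % xhat, 0);
  arma::mat corr = xhat;
  corr.each_row() %= mean_dxhat_xhat;
  dY.each_row() -= mean_dxhat;
  dY -= corr;
  dY.each_row() %= inv;
  dY.reshape(n, m * C / n);
  return List::create(_["dX"] = dY, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// One Adagrad step over parallel lists of parameters, gradients and
// accumulators. Allocates fresh outputs (no aliasing with the inputs);
// dim attributes are preserved.
// [[Rcpp::export]]
List cpp_adagrad_step(List params, List grads, List acc, double lr,
                      double eps) {
  CharacterVector nms = grads.names();
  for (R_xlen_t j = 0; j < nms.size(); ++j) {
    std::string nm = as<std::string>(nms[j]);
    NumericVector g = grads[nm], a = acc[nm], w = params[nm];
    R_xlen_t len = g.size();
    NumericVector a2(len), w2(len);
    for (R_xlen_t i = 0; i < len; ++i) {
      a2[i] = a[i] + g[i] * g[i];
      w2[i] = w[i] - lr * g[i] / (std::sqrt(a2[i]) + eps);
    }
    a2.attr("dim") = a.attr("dim");
    w2.attr("dim") = w.attr("dim");
    acc[nm] = a2;
    params[nm] = w2;
  }
  return List::create(_["params"] = params, _["acc"] = acc);
}
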