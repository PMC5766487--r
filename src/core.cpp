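// Compiled kernels: biquad-cascade filtering and the recurrent MLP
// (forward simulation + exact Jacobian by real-time recurrent learning).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form II transposed cascade of second-order sections.
// sos: n_sections x 6 rows (b0 b1 b2 a0 a1 a2), a0 == 1 assumed.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow(), n = x.size();
  NumericVector y(n);
  std::vector<double> s1(ns, 0.0), s2(ns, 0.0);
  for (int t = 0; t < n; ++t) {
    double v = x[t];
    for (int k = 0; k < ns; ++k) {
      const double b0 = sos(k, 0), b1 = sos(k, 1), b2 = sos(k, 2);
      const double a1 = sos(k, 4), a2 = sos(k, 5);
      const double w = b0 * v + s1[k];
      s1[k] = b1 * v - a1 * w + s2[k];
      s2[k] = b2 * v - a2 * w;
      v = w;
    }
    y[t] = v;
  }
  return y;
}

static inline double sigmoid(double a) { return 1.0 / (1.0 + std::exp(-a)); }

// Forward simulation of the two-hidden-layer recurrent MLP:
//   y1(t) = f(W1' x(t) + V1' y1(t-1) + U1' y1(t-2) + b1)
//   y2(t) = f(W2' y1(t) + V2' y2(t-1) + U2' y2(t-2) + b2)
//   out(t) = C' y2(t)
// Hidden states before t = 1 are zero.
// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& W1, const arma::mat& V1, const arma::mat& U1,
                     const arma::vec& b1, const arma::mat& W2, const arma::mat& V2,
                     const arma::mat& U2, const arma::vec& b2, const arma::mat& C,
                     const arma::mat& X) {
  const arma::uword T = X.n_rows, q = W1.n_cols, r = W2.n_cols, m = C.n_cols;
  arma::mat Y1(T, q), Y2(T, r), Out(T, m);
  arma::vec y1p1(q, arma::fill::zeros), y1p2(q, arma::fill::zeros);
  arma::vec y2p1(r, arma::fill::zeros), y2p2(r, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec a1 = W1.t() * X.row(t).t() + V1.t() * y1p1 + U1.t() * y1p2 + b1;
    arma::vec y1 = 1.0 / (1.0 + arma::exp(-a1));
    arma::vec a2 = W2.t() * y1 + V2.t() * y2p1 + U2.t() * y2p2 + b2;
    arma::vec y2 = 1.0 / (1.0 + arma::exp(-a2));
    Out.row(t) = (C.t() * y2).t();
    Y1.row(t) = y1.t();
    Y2.row(t) = y2.t();
    y1p2 = y1p1; y1p1 = y1;
    y2p2 = y2p1; y2p1 = y2;
  }
  return List::create(_["outputs"] = Out, _["y1"] = Y1, _["y2"] = Y2);
}

// Exact Jacobian of all residuals w.r.t. the flattened weight vector, by
// forward sensitivity propagation (RTRL) through the full sequence.
// Weight vector layout (column-major within each block):
//   W1 (p*q) | V1 (q*q) | U1 (q*q) | b1 (q) | W2 (q*r) | V2 (r*r) |
//   U2 (r*r) | b2 (r) | C (r*m)
// Residual rows are ordered time-major: (t, output 1..m) for t > burn_in.
// [[Rcpp::export]]
List rnn_jacobian_cpp(const arma::mat& W1, const arma::mat& V1, const arma::mat& U1,
                      const arma::vec& b1, const arma::mat& W2, const arma::mat& V2,
                      const arma::mat& U2, const arma::vec& b2, const arma::mat& C,
                      const arma::mat& X, const arma::mat& Tg, const int burn_in) {
  const arma::uword T = X.n_rows, p = W1.n_rows, q = W1.n_cols,
                    r = W2.n_cols, m = C.n_cols;
  const arma::uword oW1 = 0, oV1 = oW1 + p * q, oU1 = oV1 + q * q,
                    ob1 = oU1 + q * q, oW2 = ob1 + q, oV2 = oW2 + q * r,
                    oU2 = oV2 + r * r, ob2 = oU2 + r * r, oC = ob2 + r,
                    W = oC + r * m;
  const arma::uword burn = std::min<arma::uword>(burn_in, T);
  const arma::uword nres = (T - burn) * m;
  arma::mat J(nres, W, arma::fill::zeros);
  arma::vec res(nres);

  arma::vec y1p1(q, arma::fill::zeros), y1p2(q, arma::fill::zeros);
  arma::vec y2p1(r, arma::fill::zeros), y2p2(r, arma::fill::zeros);
  arma::mat S1(q, W, arma::fill::zeros), S1p1(q, W, arma::fill::zeros),
            S1p2(q, W, arma::fill::zeros);
  arma::mat S2(r, W, arma::fill::zeros), S2p1(r, W, arma::fill::zeros),
            S2p2(r, W, arma::fill::zeros);

  for (arma::uword t = 0; t < T; ++t) {
    const arma::vec xt = X.row(t).t();
    arma::vec a1 = W1.t() * xt + V1.t() * y1p1 + U1.t() * y1p2 + b1;
    arma::vec y1 = 1.0 / (1.0 + arma::exp(-a1));
    arma::vec d1 = y1 % (1.0 - y1);

    // layer-1 sensitivities: recurrent carry plus direct weight derivatives
    S1 = V1.t() * S1p1 + U1.t() * S1p2;
    for (arma::uword i = 0; i < q; ++i) {
      double* row = S1.colptr(0) + i;                 // row i, col stride q
      for (arma::uword j = 0; j < p; ++j) S1(i, oW1 + i * p + j) += xt(j);
      for (arma::uword j = 0; j < q; ++j) {
        S1(i, oV1 + i * q + j) += y1p1(j);
        S1(i, oU1 + i * q + j) += y1p2(j);
      }
      S1(i, ob1 + i) += 1.0;
      (void)row;
    }
    S1.each_col() %= d1;

    arma::vec a2 = W2.t() * y1 + V2.t() * y2p1 + U2.t() * y2p2 + b2;
    arma::vec y2 = 1.0 / (1.0 + arma::exp(-a2));
    arma::vec d2 = y2 % (1.0 - y2);

    S2 = W2.t() * S1 + V2.t() * S2p1 + U2.t() * S2p2;
    for (arma::uword i = 0; i < r; ++i) {
      for (arma::uword j = 0; j < q; ++j) S2(i, oW2 + i * q + j) += y1(j);
      for (arma::uword j = 0; j < r; ++j) {
        S2(i, oV2 + i * r + j) += y2p1(j);
        S2(i, oU2 + i * r + j) += y2p2(j);
      }
      S2(i, ob2 + i) += 1.0;
    }
    S2.each_col() %= d2;

    if (t >= burn) {
      const arma::uword base = (t - burn) * m;
      const arma::vec out = C.t() * y2;
      for (arma::uword k = 0; k < m; ++k) {
        res(base + k) = out(k) - Tg(t, k);
        J.row(base + k) = (C.col(k).t() * S2);
        for (arma::uword j = 0; j < r; ++j) J(base + k, oC + k * r + j) += y2(j);
      }
    }

    y1p2 = y1p1; y1p1 = y1;
    y2p2 = y2p1; y2p1 = y2;
    S1p2 = S1p1; S1p1 = S1;
    S2p2 = S2p1; S2p1 = S2;
  }
  return List::create(_["residuals"] = res, _["J"] = J);
}
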