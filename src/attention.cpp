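// Fused multi-head self-attention forward/backward.
//
// X is a vertical stack of B subject blocks, each T tokens of width d
// (d = H * dh). Scores and softmax are computed per subject and head; the
// backward pass recomputes the (cheap) softmax from Q and K instead of
// carrying the B*H*T x T attention matrix across the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat proj(const mat& X, const mat& W, const rowvec& b) {
  mat out = X * W;
  out.each_row() += b;
  return out;
}

static inline mat softmax_block(const mat& Qb, const mat& Kb, double scale) {
  mat S = Qb * Kb.t() * scale;
  S.each_col() -= max(S, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// [[Rcpp::export]]
Rcpp::List attn_forward(const arma::mat& X,
                        const arma::mat& Wq, const arma::rowvec& bq,
                        const arma::mat& Wk, const arma::rowvec& bk,
                        const arma::mat& Wv, const arma::rowvec& bv,
                        const int H, const int T) {
  const int d = X.n_cols;
  const int dh = d / H;
  const int B = X.n_rows / T;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat Q = proj(X, Wq, bq), K = proj(X, Wk, bk), V = proj(X, Wv, bv);
  mat O(X.n_rows, d);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = (b + 1) * T - 1;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat S = softmax_block(Q.submat(r0, c0, r1, c1),
                            K.submat(r0, c0, r1, c1), scale);
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("Q") = Q,
                            Rcpp::Named("K") = K, Rcpp::Named("V") = V);
}

// [[Rcpp::export]]
Rcpp::List attn_backward(const arma::mat& gO,
                         const arma::mat& Q, const arma::mat& K,
                         const arma::mat& V, const arma::mat& X,
                         const arma::mat& Wq, const arma::mat& Wk,
                         const arma::mat& Wv, const int H, const int T) {
  const int d = X.n_cols;
  const int dh = d / H;
  const int B = X.n_rows / T;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat gQ(size(Q), fill::zeros), gK(size(K), fill::zeros),
      gV(size(V), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = (b + 1) * T - 1;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh, c1 = (h + 1) * dh - 1;
      const mat Qbh = Q.submat(r0, c0, r1, c1);
      const mat Kbh = K.submat(r0, c0, r1, c1);
      const mat Pbh = softmax_block(Qbh, Kbh, scale);
      const mat gObh = gO.submat(r0, c0, r1, c1);
      const mat Vbh = V.submat(r0, c0, r1, c1);
      mat gP = gObh * Vbh.t();
      gV.submat(r0, c0, r1, c1) = Pbh.t() * gObh;
      gP.each_col() -= sum(gP % Pbh, 1);   // softmax backward (row-wise)
      mat gS = Pbh % gP;
      gQ.submat(r0, c0, r1, c1) = gS * Kbh * scale;
      gK.submat(r0, c0, r1, c1) = gS.t() * Qbh * scale;
    }
  }
  mat gX = gQ * Wq.t() + gK * Wk.t() + gV * Wv.t();
  return Rcpp::List::create(
      Rcpp::Named("gX") = gX,
      Rcpp::Named("gWq") = X.t() * gQ, Rcpp::Named("gbq") = sum(gQ, 0),
      Rcpp::Named("gWk") = X.t() * gK, Rcpp::Named("gbk") = sum(gK, 0),
      Rcpp::Named("gWv") = X.t() * gV, Rcpp::Named("gbv") = sum(gV, 0));
}
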