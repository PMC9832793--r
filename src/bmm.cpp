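// Batched small-matrix products for multi-head self-attention.
//
// A and B are vertical stacks of G equally sized blocks; the result is the
// stack of per-block products. Used for the score (Q K^T) and the
// attention-weighted value (P V) steps, where the per-subject block shapes
// are too small for one flat BLAS call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// op: 0 = A_g * B_g^T, 1 = A_g * B_g, 2 = A_g^T * B_g
// [[Rcpp::export]]
arma::mat bmm_blocks(const arma::mat& A, const arma::mat& B,
                     const int G, const int op) {
  const int ra = A.n_rows / G;
  const int rb = B.n_rows / G;
  int out_r, out_c;
  if (op == 0)      { out_r = ra;       out_c = rb; }
  else if (op == 1) { out_r = ra;       out_c = B.n_cols; }
  else              { out_r = A.n_cols; out_c = B.n_cols; }
  mat out(out_r * G, out_c);
  for (int g = 0; g < G; ++g) {
    const mat Ag = A.rows(g * ra, (g + 1) * ra - 1);
    const mat Bg = B.rows(g * rb, (g + 1) * rb - 1);
    if (op == 0)      out.rows(g * out_r, (g + 1) * out_r - 1) = Ag * Bg.t();
    else if (op == 1) out.rows(g * out_r, (g + 1) * out_r - 1) = Ag * Bg;
    else              out.rows(g * out_r, (g + 1) * out_r - 1) = Ag.t() * Bg;
  }
  return out;
}
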