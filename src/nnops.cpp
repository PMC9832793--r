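// Elementwise and row-wise kernels for the network hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SELU_L = 1.0507009873554805;
static const double SELU_A = 1.6732632423543772;

// [[Rcpp::export]]
arma::mat selu_fwd(const arma::mat& x) {
  mat out(size(x));
  const double* px = x.memptr();
  double* po = out.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i)
    po[i] = px[i] > 0 ? SELU_L * px[i] : SELU_L * SELU_A * (std::exp(px[i]) - 1);
  return out;
}

// gradient from the forward VALUE: d/dx = L for x>0, val + L*A otherwise
// [[Rcpp::export]]
arma::mat selu_bwd(const arma::mat& val, const arma::mat& g) {
  mat out(size(val));
  const double* pv = val.memptr();
  const double* pg = g.memptr();
  double* po = out.memptr();
  const uword n = val.n_elem;
  for (uword i = 0; i < n; ++i)
    po[i] = pg[i] * (pv[i] > 0 ? SELU_L : pv[i] + SELU_L * SELU_A);
  return out;
}

// [[Rcpp::export]]
Rcpp::List layernorm_fwd(const arma::mat& x, const arma::rowvec& gam,
                         const arma::rowvec& shift, const double eps) {
  mat xc = x.each_col() - mean(x, 1);
  vec inv = 1.0 / sqrt(mean(square(xc), 1) + eps);
  mat xhat = xc.each_col() % inv;
  mat val = xhat.each_row() % gam;
  val.each_row() += shift;
  return Rcpp::List::create(Rcpp::Named("val") = val,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layernorm_bwd(const arma::mat& g, const arma::mat& xhat,
                         const arma::vec& inv, const arma::rowvec& gam) {
  rowvec ggain = sum(g % xhat, 0);
  rowvec gshift = sum(g, 0);
  mat dxhat = g.each_row() % gam;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat gx = dxhat;
  gx.each_col() -= m1;
  gx -= xhat.each_col() % m2;
  gx.each_col() %= inv;
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggain") = ggain,
                            Rcpp::Named("gshift") = gshift);
}
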