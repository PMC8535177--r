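// Batched GRU time-loop kernels.
//
// Layout contract shared with the R side: a sequence batch of B sessions and
// T timesteps is a (T*B) x u matrix whose row (t-1)*B + b holds item b at
// step t. Input projections (x W + bias) are precomputed in R with one large
// matrix product; these kernels only run the recurrence.
//
// Update rule (Cho et al. variant):
//   z_t = sigmoid(xz_t + h_{t-1} Uz)
//   r_t = sigmoid(xr_t + h_{t-1} Ur)
//   g_t = tanh(xh_t + (r_t * h_{t-1}) Uh)
//   h_t = (1 - z_t) * h_{t-1} + z_t * g_t
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(const arma::mat& Xz, const arma::mat& Xr,
                           const arma::mat& Xh, const arma::mat& Uz,
                           const arma::mat& Ur, const arma::mat& Uh,
                           const int B) {
  const int u = Xz.n_cols;
  const int T = Xz.n_rows / B;
  mat H(T * B, u), Z(T * B, u), Rg(T * B, u), G(T * B, u);
  mat h(B, u, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    mat z = sigm(Xz.rows(r0, r1) + h * Uz);
    mat r = sigm(Xr.rows(r0, r1) + h * Ur);
    mat g = tanh(Xh.rows(r0, r1) + (r % h) * Uh);
    mat hn = (1.0 - z) % h + z % g;
    Z.rows(r0, r1) = z; Rg.rows(r0, r1) = r; G.rows(r0, r1) = g;
    H.rows(r0, r1) = hn;
    h = hn;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = Rg, Rcpp::Named("G") = G);
}

// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(const arma::mat& dH, const arma::mat& H,
                            const arma::mat& Z, const arma::mat& Rg,
                            const arma::mat& G, const arma::mat& Uz,
                            const arma::mat& Ur, const arma::mat& Uh,
                            const int B) {
  const int u = H.n_cols;
  const int T = H.n_rows / B;
  mat dXz(T * B, u), dXr(T * B, u), dXh(T * B, u);
  mat dUz(u, u, fill::zeros), dUr(u, u, fill::zeros), dUh(u, u, fill::zeros);
  mat carry(B, u, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    mat hprev = (t == 0) ? mat(B, u, fill::zeros)
                         : mat(H.rows(r0 - B, r1 - B));
    mat z = Z.rows(r0, r1), r = Rg.rows(r0, r1), g = G.rows(r0, r1);
    mat dh = dH.rows(r0, r1) + carry;

    mat dz = dh % (g - hprev);
    mat dg = dh % z;
    mat dhprev = dh % (1.0 - z);

    mat dag = dg % (1.0 - g % g);
    dXh.rows(r0, r1) = dag;
    dUh += (r % hprev).t() * dag;
    mat dq = dag * Uh.t();          // q = r * hprev
    mat dr = dq % hprev;
    dhprev += dq % r;

    mat daz = dz % z % (1.0 - z);
    dXz.rows(r0, r1) = daz;
    dUz += hprev.t() * daz;
    dhprev += daz * Uz.t();

    mat dar = dr % r % (1.0 - r);
    dXr.rows(r0, r1) = dar;
    dUr += hprev.t() * dar;
    dhprev += dar * Ur.t();

    carry = dhprev;
  }
  return Rcpp::List::create(
      Rcpp::Named("dXz") = dXz, Rcpp::Named("dXr") = dXr,
      Rcpp::Named("dXh") = dXh, Rcpp::Named("dUz") = dUz,
      Rcpp::Named("dUr") = dUr, Rcpp::Named("dUh") = dUh);
}
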