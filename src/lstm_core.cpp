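// Compiled LSTM sequence kernels. The cell update mirrors lstm_step() in
// R/lstm.R exactly; equality of the two implementations is asserted in the
// test suite. Layout: batches are rows, time is the cube's slice index.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline mat gate_pre(const mat& x, const mat& h, const mat& U,
                           const mat& W, const rowvec& b) {
  mat p = x * U + h * W;
  p.each_row() += b;
  return p;
}

// Forward over a whole sequence for one layer.
// X: n x in_dim x T input cube. Returns hidden states H (n x units x T)
// and the gate/cell caches needed for backpropagation through time.
// [[Rcpp::export]]
Rcpp::List lstm_layer_forward_cpp(const arma::cube& X,
                                  const arma::mat& Uf, const arma::mat& Ui,
                                  const arma::mat& Uo, const arma::mat& Ug,
                                  const arma::mat& Wf, const arma::mat& Wi,
                                  const arma::mat& Wo, const arma::mat& Wg,
                                  const arma::rowvec& bf, const arma::rowvec& bi,
                                  const arma::rowvec& bo, const arma::rowvec& bg) {
  const uword n = X.n_rows, T = X.n_slices, units = Uf.n_cols;
  cube H(n, units, T), F(n, units, T), I(n, units, T), O(n, units, T),
      G(n, units, T), C(n, units, T);
  mat h(n, units, fill::zeros), c(n, units, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const mat& x = X.slice(t);
    mat f = sigm(gate_pre(x, h, Uf, Wf, bf));
    mat i = sigm(gate_pre(x, h, Ui, Wi, bi));
    mat o = sigm(gate_pre(x, h, Uo, Wo, bo));
    mat g = tanh(gate_pre(x, h, Ug, Wg, bg));
    c = f % c + i % g;
    h = o % tanh(c);
    F.slice(t) = f; I.slice(t) = i; O.slice(t) = o; G.slice(t) = g;
    C.slice(t) = c; H.slice(t) = h;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("F") = F, Rcpp::Named("I") = I,
      Rcpp::Named("O") = O, Rcpp::Named("G") = G, Rcpp::Named("C") = C);
}

// Backpropagation through time for one layer. dH holds the gradient of the
// loss with respect to each emitted hidden state. Returns parameter
// gradients and the gradient with respect to the layer's inputs.
// [[Rcpp::export]]
Rcpp::List lstm_layer_backward_cpp(const arma::cube& dH, const arma::cube& X,
                                   const arma::cube& H, const arma::cube& F,
                                   const arma::cube& I, const arma::cube& O,
                                   const arma::cube& G, const arma::cube& C,
                                   const arma::mat& Uf, const arma::mat& Ui,
                                   const arma::mat& Uo, const arma::mat& Ug,
                                   const arma::mat& Wf, const arma::mat& Wi,
                                   const arma::mat& Wo, const arma::mat& Wg) {
  const uword n = X.n_rows, in_dim = X.n_cols, T = X.n_slices,
              units = Uf.n_cols;
  mat gUf(in_dim, units, fill::zeros), gUi(gUf), gUo(gUf), gUg(gUf);
  mat gWf(units, units, fill::zeros), gWi(gWf), gWo(gWf), gWg(gWf);
  rowvec gbf(units, fill::zeros), gbi(gbf), gbo(gbf), gbg(gbf);
  cube dX(n, in_dim, T);
  mat dh_carry(n, units, fill::zeros), dc_carry(n, units, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& f = F.slice(t);
    const mat& i = I.slice(t);
    const mat& o = O.slice(t);
    const mat& g = G.slice(t);
    const mat& c = C.slice(t);
    mat c_prev = (t == 0) ? mat(n, units, fill::zeros) : C.slice(t - 1);
    mat h_prev = (t == 0) ? mat(n, units, fill::zeros) : H.slice(t - 1);
    mat tc = tanh(c);
    mat dh = dH.slice(t) + dh_carry;
    mat do_ = dh % tc;
    mat dc = dc_carry + dh % o % (1.0 - tc % tc);
    mat dpf = (dc % c_prev) % f % (1.0 - f);
    mat dpi = (dc % g) % i % (1.0 - i);
    mat dpo = do_ % o % (1.0 - o);
    mat dpg = (dc % i) % (1.0 - g % g);
    const mat& x = X.slice(t);
    gUf += x.t() * dpf; gUi += x.t() * dpi;
    gUo += x.t() * dpo; gUg += x.t() * dpg;
    gWf += h_prev.t() * dpf; gWi += h_prev.t() * dpi;
    gWo += h_prev.t() * dpo; gWg += h_prev.t() * dpg;
    gbf += sum(dpf, 0); gbi += sum(dpi, 0);
    gbo += sum(dpo, 0); gbg += sum(dpg, 0);
    dh_carry = dpf * Wf.t() + dpi * Wi.t() + dpo * Wo.t() + dpg * Wg.t();
    dc_carry = dc % f;
    dX.slice(t) = dpf * Uf.t() + dpi * Ui.t() + dpo * Uo.t() + dpg * Ug.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("gU") = Rcpp::List::create(
          Rcpp::Named("f") = gUf, Rcpp::Named("i") = gUi,
          Rcpp::Named("o") = gUo, Rcpp::Named("g") = gUg),
      Rcpp::Named("gW") = Rcpp::List::create(
          Rcpp::Named("f") = gWf, Rcpp::Named("i") = gWi,
          Rcpp::Named("o") = gWo, Rcpp::Named("g") = gWg),
      Rcpp::Named("gb") = Rcpp::List::create(
          Rcpp::Named("f") = gbf, Rcpp::Named("i") = gbi,
          Rcpp::Named("o") = gbo, Rcpp::Named("g") = gbg),
      Rcpp::Named("dX") = dX);
}
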