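// Minimal LSTM forward/backward kernels used by the sentence encoder and the
// character-level encoder. Rows are timesteps. Gate layout in the 4H
// dimension: [input, forget, candidate, output].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// X: T x D, Wx: D x 4H, Wh: H x 4H, b: 1 x 4H.
// Returns H_out (T x H), C (T x H), Gates (T x 4H, post-activation).
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& b) {
  const uword T = X.n_rows;
  const uword H = Wh.n_rows;
  mat Hout(T, H, fill::zeros), C(T, H, fill::zeros), G(T, 4 * H, fill::zeros);
  rowvec h_prev(H, fill::zeros), c_prev(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    rowvec pre = X.row(t) * Wx + h_prev * Wh + b;
    rowvec i = 1.0 / (1.0 + exp(-pre.cols(0, H - 1)));
    rowvec f = 1.0 / (1.0 + exp(-pre.cols(H, 2 * H - 1)));
    rowvec g = tanh(pre.cols(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + exp(-pre.cols(3 * H, 4 * H - 1)));
    rowvec c = f % c_prev + i % g;
    rowvec h = o % tanh(c);
    G(t, span(0, H - 1)) = i;
    G(t, span(H, 2 * H - 1)) = f;
    G(t, span(2 * H, 3 * H - 1)) = g;
    G(t, span(3 * H, 4 * H - 1)) = o;
    C.row(t) = c;
    Hout.row(t) = h;
    h_prev = h;
    c_prev = c;
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hout, Rcpp::Named("c") = C,
                            Rcpp::Named("gates") = G);
}

// Backpropagation through the LSTM above. dH: T x H upstream gradient on the
// hidden outputs. Returns dX and parameter gradients.
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::mat& Hout,
                             const arma::mat& C, const arma::mat& G,
                             const arma::mat& dH) {
  const uword T = X.n_rows;
  const uword H = Wh.n_rows;
  mat dX(T, X.n_cols, fill::zeros);
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  rowvec db(4 * H, fill::zeros);
  rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = T; tt > 0; --tt) {
    const uword t = tt - 1;
    rowvec i = G(t, span(0, H - 1));
    rowvec f = G(t, span(H, 2 * H - 1));
    rowvec g = G(t, span(2 * H, 3 * H - 1));
    rowvec o = G(t, span(3 * H, 4 * H - 1));
    rowvec c = C.row(t);
    rowvec c_prev = (t > 0) ? rowvec(C.row(t - 1)) : rowvec(H, fill::zeros);
    rowvec h_prev = (t > 0) ? rowvec(Hout.row(t - 1)) : rowvec(H, fill::zeros);
    rowvec tc = tanh(c);
    rowvec dh = dH.row(t) + dh_next;
    rowvec do_ = dh % tc;
    rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
    rowvec di = dc % g;
    rowvec df = dc % c_prev;
    rowvec dg = dc % i;
    dc_next = dc % f;
    rowvec dpre(4 * H);
    dpre.cols(0, H - 1) = di % i % (1.0 - i);
    dpre.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dpre.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dpre.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dX.row(t) = dpre * Wx.t();
    dh_next = dpre * Wh.t();
    dWx += X.row(t).t() * dpre;
    dWh += h_prev.t() * dpre;
    db += dpre;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
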