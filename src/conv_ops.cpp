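// Tap-wise convolution kernels for the neural-network core: gather a strided
// kernel-tap window, multiply by the tap's weight rows (BLAS via Armadillo),
// and scatter gradients back. Works for any spatial rank (2D/3D); memory
// stays O(H*W*C) because taps are processed one at a time.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct TapGeom {
  long long npos, chanstride, k_n;
  int nd, C;
  std::vector<long long> base, tapoff;
};

static TapGeom make_geom(const IntegerVector &dp, int k, int stride,
                         const IntegerVector &outdim) {
  TapGeom g;
  g.nd = dp.size() - 1;
  g.C = dp[g.nd];
  std::vector<long long> strides(g.nd);
  long long acc = 1;
  for (int i = 0; i < g.nd; ++i) { strides[i] = acc; acc *= dp[i]; }
  g.chanstride = acc;
  g.npos = 1;
  for (int i = 0; i < g.nd; ++i) g.npos *= outdim[i];
  g.base.resize(g.npos);
  for (long long p = 0; p < g.npos; ++p) {
    long long rem = p, idx = 0;
    for (int i = 0; i < g.nd; ++i) {
      long long pos = rem % outdim[i]; rem /= outdim[i];
      idx += pos * (long long)stride * strides[i];
    }
    g.base[p] = idx;
  }
  g.k_n = 1;
  for (int i = 0; i < g.nd; ++i) g.k_n *= k;
  g.tapoff.resize(g.k_n);
  for (long long t = 0; t < g.k_n; ++t) {
    long long rem = t, off = 0;
    for (int i = 0; i < g.nd; ++i) {
      long long pos = rem % k; rem /= k;
      off += pos * strides[i];
    }
    g.tapoff[t] = off;
  }
  return g;
}

static void gather(const double *xp, const TapGeom &g, long long t,
                   arma::mat &Vm) {
  for (int c = 0; c < g.C; ++c) {
    const double *src = xp + g.tapoff[t] + (long long)c * g.chanstride;
    double *col = Vm.colptr(c);
    for (long long p = 0; p < g.npos; ++p) col[p] = src[g.base[p]];
  }
}

// [[Rcpp::export]]
arma::mat conv_forward_cpp(NumericVector xp, IntegerVector dp, int k,
                           int stride, IntegerVector outdim,
                           const arma::mat &W, const arma::rowvec &b) {
  TapGeom g = make_geom(dp, k, stride, outdim);
  int Cout = W.n_cols;
  arma::mat Y(g.npos, Cout, arma::fill::zeros);
  arma::mat Vm(g.npos, g.C), Wt(g.C, Cout);
  const double *x = xp.begin();
  for (long long t = 0; t < g.k_n; ++t) {
    gather(x, g, t, Vm);
    for (int c = 0; c < g.C; ++c) Wt.row(c) = W.row(t + (long long)c * g.k_n);
    Y += Vm * Wt;
  }
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
List conv_backward_cpp(NumericVector xp, IntegerVector dp, int k, int stride,
                       IntegerVector outdim, const arma::mat &W,
                       const arma::mat &dY) {
  TapGeom g = make_geom(dp, k, stride, outdim);
  int Cout = W.n_cols;
  arma::mat dW(W.n_rows, Cout, arma::fill::zeros);
  NumericVector dxp(xp.size());
  arma::mat Vm(g.npos, g.C), Wt(g.C, Cout);
  const double *x = xp.begin();
  double *dx = dxp.begin();
  for (long long t = 0; t < g.k_n; ++t) {
    gather(x, g, t, Vm);
    arma::mat dWt = Vm.t() * dY;              // C x Cout
    for (int c = 0; c < g.C; ++c) Wt.row(c) = W.row(t + (long long)c * g.k_n);
    for (int c = 0; c < g.C; ++c) dW.row(t + (long long)c * g.k_n) = dWt.row(c);
    arma::mat dV = dY * Wt.t();               // npos x C
    for (int c = 0; c < g.C; ++c) {
      double *dst = dx + g.tapoff[t] + (long long)c * g.chanstride;
      const double *col = dV.colptr(c);
      for (long long p = 0; p < g.npos; ++p) dst[g.base[p]] += col[p];
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(Named("dxp") = dxp, Named("dW") = dW,
                      Named("db") = NumericVector(db.begin(), db.end()));
}

// second-order pass for the gradient penalty: forward-convolve s (no bias)
// and accumulate dP/dW = gather(s)' * dY per tap
// [[Rcpp::export]]
List conv_gradgrad_cpp(NumericVector sp, IntegerVector dp, int k, int stride,
                       IntegerVector outdim, const arma::mat &W,
                       const arma::mat &dY) {
  TapGeom g = make_geom(dp, k, stride, outdim);
  int Cout = W.n_cols;
  arma::mat Sout(g.npos, Cout, arma::fill::zeros);
  arma::mat dW2(W.n_rows, Cout, arma::fill::zeros);
  arma::mat Sm(g.npos, g.C), Wt(g.C, Cout);
  const double *s = sp.begin();
  for (long long t = 0; t < g.k_n; ++t) {
    gather(s, g, t, Sm);
    for (int c = 0; c < g.C; ++c) Wt.row(c) = W.row(t + (long long)c * g.k_n);
    Sout += Sm * Wt;
    arma::mat dWt = Sm.t() * dY;
    for (int c = 0; c < g.C; ++c) dW2.row(t + (long long)c * g.k_n) = dWt.row(c);
  }
  return List::create(Named("s_out") = Sout, Named("dW") = dW2);
}
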