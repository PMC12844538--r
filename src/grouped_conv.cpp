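// Grouped 1-D convolution kernels ("same" padding) used by the CNN
// branches of the fusion model. One primitive covers the three layer kinds:
// ordinary convolution (groups = 1), depthwise convolution with a depth
// multiplier (groups = Cin) and pointwise mixing (k = 1, groups = 1).
//
// Layout conventions (column-major, matching R):
//   x  : L x Cin matrix, time down the rows, one column per channel
//   w  : array k x cin_g x Cout flattened to a vector, where
//        cin_g = Cin / groups and output channel o belongs to group
//        g = o / (Cout / groups), reading input channels g*cin_g .. +cin_g-1
//   y  : L x Cout ("same" length; pad_left zeros implicit on the left,
//        k - 1 - pad_left on the right)

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix conv1d_fwd(const NumericMatrix& x, const NumericVector& w,
                         const NumericVector& bias, int k, int groups,
                         int pad_left) {
  const int L = x.nrow(), Cin = x.ncol(), Cout = bias.size();
  const int cin_g = Cin / groups, cout_g = Cout / groups;
  NumericMatrix y(L, Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int o = 0; o < Cout; ++o) {
    double* yo = yp + (size_t)L * o;
    const double b = bias[o];
    for (int t = 0; t < L; ++t) yo[t] = b;
    const int g = o / cout_g;
    for (int cg = 0; cg < cin_g; ++cg) {
      const double* xc = xp + (size_t)L * (g * cin_g + cg);
      const double* wo = wp + (size_t)k * (cg + (size_t)cin_g * o);
      for (int j = 0; j < k; ++j) {
        const double wv = wo[j];
        const int s = j - pad_left;
        const int t0 = s < 0 ? -s : 0;
        const int t1 = s > 0 ? L - s : L;
        for (int t = t0; t < t1; ++t) yo[t] += wv * xc[t + s];
      }
    }
  }
  return y;
}

// Gradient w.r.t. the input. dy: L x Cout.
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_x(const NumericMatrix& dy, const NumericVector& w,
                           int k, int groups, int pad_left, int cin) {
  const int L = dy.nrow(), Cout = dy.ncol();
  const int cin_g = cin / groups, cout_g = Cout / groups;
  NumericMatrix dx(L, cin);
  const double* dyp = dy.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();
  for (int o = 0; o < Cout; ++o) {
    const double* dyo = dyp + (size_t)L * o;
    const int g = o / cout_g;
    for (int cg = 0; cg < cin_g; ++cg) {
      double* dxc = dxp + (size_t)L * (g * cin_g + cg);
      const double* wo = wp + (size_t)k * (cg + (size_t)cin_g * o);
      for (int j = 0; j < k; ++j) {
        const double wv = wo[j];
        const int s = j - pad_left;
        const int t0 = s < 0 ? -s : 0;
        const int t1 = s > 0 ? L - s : L;
        for (int t = t0; t < t1; ++t) dxc[t + s] += wv * dyo[t];
      }
    }
  }
  return dx;
}

// Gradients w.r.t. weights and bias.
// [[Rcpp::export]]
List conv1d_bwd_w(const NumericMatrix& x, const NumericMatrix& dy, int k,
                  int groups, int pad_left) {
  const int L = x.nrow(), Cin = x.ncol(), Cout = dy.ncol();
  const int cin_g = Cin / groups, cout_g = Cout / groups;
  NumericVector gw((size_t)k * cin_g * Cout);
  NumericVector gb(Cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* gwp = gw.begin();
  for (int o = 0; o < Cout; ++o) {
    const double* dyo = dyp + (size_t)L * o;
    double acc = 0.0;
    for (int t = 0; t < L; ++t) acc += dyo[t];
    gb[o] = acc;
    const int g = o / cout_g;
    for (int cg = 0; cg < cin_g; ++cg) {
      const double* xc = xp + (size_t)L * (g * cin_g + cg);
      double* gwo = gwp + (size_t)k * (cg + (size_t)cin_g * o);
      for (int j = 0; j < k; ++j) {
        const int s = j - pad_left;
        const int t0 = s < 0 ? -s : 0;
        const int t1 = s > 0 ? L - s : L;
        double a = 0.0;
        for (int t = t0; t < t1; ++t) a += xc[t + s] * dyo[t];
        gwo[j] = a;
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(k, cin_g, Cout);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
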