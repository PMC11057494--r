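// Minimal dense conv-net kernels used by the atrous segmentation network.
// Tensors are R double arrays, column-major, dim (H, W, C, N).
// Convolutions are im2col + GEMM (Armadillo/BLAS); dilation ("atrous" rate),
// stride and zero padding are supported. Backward passes return exact
// gradients for the same layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int out_dim(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill the im2col matrix (K x P, K = KH*KW*Cin, P = Ho*Wo) for sample n.
static void im2col(const double *x, int H, int W, int Cin, int n,
                   int KH, int KW, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat &col) {
  const double *xs = x + (size_t)H * W * Cin * n;
  for (int c = 0; c < Cin; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int k = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            int p = ho + Ho * wo;
            col(k, p) = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                            ? xs[hi + (size_t)H * (wi + (size_t)W * c)]
                            : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_acc(double *gx, int H, int W, int Cin, int n,
                       int KH, int KW, int stride, int pad, int dil,
                       int Ho, int Wo, const arma::mat &gcol) {
  double *gs = gx + (size_t)H * W * Cin * n;
  for (int c = 0; c < Cin; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int k = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            gs[hi + (size_t)H * (wi + (size_t)W * c)] += gcol(k, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: channel mismatch");
  int Ho = out_dim(H, KH, stride, pad, dil), Wo = out_dim(W, KW, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  int K = KH * KW * Cin, P = Ho * Wo;
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, n, KH, KW, stride, pad, dil, Ho, Wo, col);
    arma::mat ym = Wm.t() * col; // Cout x P
    double *yn = y.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < P; ++p) yn[p + (size_t)P * co] = ym(co, p) + b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int K = KH * KW * Cin, P = Ho * Wo;
  NumericVector gx = alloc4(H, W, Cin, N);
  NumericVector gw = alloc4(KH, KW, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::mat col(K, P), gym(Cout, P);
  for (int n = 0; n < N; ++n) {
    const double *gn = gy.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < P; ++p) gym(co, p) = gn[p + (size_t)P * co];
    im2col(x.begin(), H, W, Cin, n, KH, KW, stride, pad, dil, Ho, Wo, col);
    Gw += col * gym.t();
    arma::mat gcol = Wm * gym; // K x P
    col2im_acc(gx.begin(), H, W, Cin, n, KH, KW, stride, pad, dil, Ho, Wo, gcol);
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gym.row(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct BilinW { int i0, i1; double w0, w1; };

static std::vector<BilinW> bilin_weights(int n_out, int n_in) {
  std::vector<BilinW> v(n_out);
  double f = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * f - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s), i1 = std::min(i0 + 1, n_in - 1);
    double w1 = s - i0;
    v[o] = {i0, i1, 1.0 - w1, w1};
  }
  return v;
}

// [[Rcpp::export]]
NumericVector bilinear_up_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  auto rh = bilin_weights(Ho, H), rw = bilin_weights(Wo, W);
  NumericVector y = alloc4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const BilinW &a = rh[ho], &b = rw[wo];
          ys[ho + (size_t)Ho * wo] =
              b.w0 * (a.w0 * xs[a.i0 + (size_t)H * b.i0] + a.w1 * xs[a.i1 + (size_t)H * b.i0]) +
              b.w1 * (a.w0 * xs[a.i0 + (size_t)H * b.i1] + a.w1 * xs[a.i1 + (size_t)H * b.i1]);
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_up_bwd(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  auto rh = bilin_weights(Ho, H), rw = bilin_weights(Wo, W);
  NumericVector gx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *gs = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double *gyn = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const BilinW &a = rh[ho], &b = rw[wo];
          double g = gyn[ho + (size_t)Ho * wo];
          gs[a.i0 + (size_t)H * b.i0] += a.w0 * b.w0 * g;
          gs[a.i1 + (size_t)H * b.i0] += a.w1 * b.w0 * g;
          gs[a.i0 + (size_t)H * b.i1] += a.w0 * b.w1 * g;
          gs[a.i1 + (size_t)H * b.i1] += a.w1 * b.w1 * g;
        }
    }
  return gx;
}
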