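// Minimal convolution engine backing the dual-GAN networks.
//
// Layout conventions (R column-major):
//   2D activations: dim (H, W, C, N)
//   2D weights:     dim (kh, kw, Cin, Cout)
//   3D activations: dim (H, W, D, C, N)
//   3D weights:     dim (kh, kw, kd, Cin, Cout)
//
// The three primitives per dimensionality (forward, grad-input, grad-weight)
// are sufficient for plain convolution, transposed convolution (= grad-input
// of a convolution), and for double backpropagation through the WGAN
// gradient-penalty term (grad-input's adjoint is the forward map, and its
// weight gradient reuses the grad-weight kernel with the roles of input and
// output swapped).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------- 2D ----

static void im2col2d(const double* im, int H, int W, int C,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*C) x (Ho*Wo)
  for (int c = 0; c < C; ++c) {
    const double* imc = im + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + j;
          double* dst = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[(size_t)ho * col.n_rows] = 0.0;
            continue;
          }
          const double* src = imc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * sh - ph + i;
            dst[(size_t)ho * col.n_rows] =
              (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& col, int H, int W, int C,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int Ho, int Wo, double* im) {
  for (int c = 0; c < C; ++c) {
    double* imc = im + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + j;
          if (wi < 0 || wi >= W) continue;
          const double* src = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)wo * Ho;
          double* dst = imc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * sh - ph + i;
            if (hi >= 0 && hi < H) dst[hi] += src[(size_t)ho * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, weight expects %d", C, Cin);
  int Ho = out_extent(H, kh, sh, ph), Wo = out_extent(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty (input %dx%d, kernel %dx%d)", H, W, kh, kw);
  int K = kh * kw * C, S = Ho * Wo;
  NumericVector y(S * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C,
             kh, kw, sh, sw, ph, pw, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)n * S * Cout, S, Cout, false, true);
    Y = col.t() * Wm;
    if (b.size() == Cout) for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_gradin(NumericVector gy, NumericVector w,
                                int sh, int sw, int ph, int pw,
                                int H, int W) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("channel mismatch in grad-input");
  int K = kh * kw * Cin, S = Ho * Wo;
  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * S * Cout, S, Cout, false, true);
    col = Wm * GY.t();
    col2im2d(col, H, W, Cin, kh, kw, sh, sw, ph, pw, Ho, Wo,
             gx.begin() + (size_t)n * H * W * Cin);
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_conv2d_gradw(NumericVector x, NumericVector gy,
                      int sh, int sw, int ph, int pw, int kh, int kw) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  int K = kh * kw * C, S = Ho * Wo;
  NumericVector gw((size_t)K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C,
             kh, kw, sh, sw, ph, pw, Ho, Wo, col);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * S * Cout, S, Cout, false, true);
    GW += col * GY;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(GY.col(o));
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------- 3D ----

static void im2col3d(const double* im, int H, int W, int D, int C,
                     int kh, int kw, int kd, int sh, int sw, int sd,
                     int ph, int pw, int pd,
                     int Ho, int Wo, int Do, arma::mat& col) {
  // col: (kh*kw*kd*C) x (Ho*Wo*Do)
  const size_t R = col.n_rows;
  for (int c = 0; c < C; ++c) {
    const double* imc = im + (size_t)c * H * W * D;
    for (int l = 0; l < kd; ++l)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          size_t row = i + (size_t)kh * (j + (size_t)kw * (l + (size_t)kd * c));
          for (int dO = 0; dO < Do; ++dO) {
            int di = dO * sd - pd + l;
            bool dok = (di >= 0 && di < D);
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * sw - pw + j;
              bool wok = (wi >= 0 && wi < W);
              size_t colbase = (size_t)(wo + Wo * dO) * Ho;
              double* dst = col.memptr() + row + R * colbase;
              if (!dok || !wok) {
                for (int ho = 0; ho < Ho; ++ho) dst[(size_t)ho * R] = 0.0;
                continue;
              }
              const double* src = imc + ((size_t)di * W + wi) * H;
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * sh - ph + i;
                dst[(size_t)ho * R] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
              }
            }
          }
        }
  }
}

static void col2im3d(const arma::mat& col, int H, int W, int D, int C,
                     int kh, int kw, int kd, int sh, int sw, int sd,
                     int ph, int pw, int pd,
                     int Ho, int Wo, int Do, double* im) {
  const size_t R = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double* imc = im + (size_t)c * H * W * D;
    for (int l = 0; l < kd; ++l)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          size_t row = i + (size_t)kh * (j + (size_t)kw * (l + (size_t)kd * c));
          for (int dO = 0; dO < Do; ++dO) {
            int di = dO * sd - pd + l;
            if (di < 0 || di >= D) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * sw - pw + j;
              if (wi < 0 || wi >= W) continue;
              size_t colbase = (size_t)(wo + Wo * dO) * Ho;
              const double* src = col.memptr() + row + R * colbase;
              double* dst = imc + ((size_t)di * W + wi) * H;
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * sh - ph + i;
                if (hi >= 0 && hi < H) dst[hi] += src[(size_t)ho * R];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4];
  int kh = wd[0], kw = wd[1], kd = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("channel mismatch: input has %d, weight expects %d", C, Cin);
  int sh = stride[0], sw = stride[1], sd = stride[2];
  int ph = pad[0], pw = pad[1], pd = pad[2];
  int Ho = out_extent(H, kh, sh, ph), Wo = out_extent(W, kw, sw, pw),
      Do = out_extent(D, kd, sd, pd);
  if (Ho < 1 || Wo < 1 || Do < 1) stop("conv output would be empty");
  size_t K = (size_t)kh * kw * kd * C, S = (size_t)Ho * Wo * Do;
  NumericVector y(S * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (size_t)n * H * W * D * C, H, W, D, C,
             kh, kw, kd, sh, sw, sd, ph, pw, pd, Ho, Wo, Do, col);
    arma::mat Y(y.begin() + (size_t)n * S * Cout, S, Cout, false, true);
    Y = col.t() * Wm;
    if (b.size() == Cout) for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_gradin(NumericVector gy, NumericVector w,
                                IntegerVector stride, IntegerVector pad,
                                IntegerVector insize) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  int Ho = gd[0], Wo = gd[1], Do = gd[2], Cout = gd[3], N = gd[4];
  int kh = wd[0], kw = wd[1], kd = wd[2], Cin = wd[3];
  if (wd[4] != Cout) stop("channel mismatch in grad-input");
  int H = insize[0], W = insize[1], D = insize[2];
  int sh = stride[0], sw = stride[1], sd = stride[2];
  int ph = pad[0], pw = pad[1], pd = pad[2];
  size_t K = (size_t)kh * kw * kd * Cin, S = (size_t)Ho * Wo * Do;
  NumericVector gx((size_t)H * W * D * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, D, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * S * Cout, S, Cout, false, true);
    col = Wm * GY.t();
    col2im3d(col, H, W, D, Cin, kh, kw, kd, sh, sw, sd, ph, pw, pd,
             Ho, Wo, Do, gx.begin() + (size_t)n * H * W * D * Cin);
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_conv3d_gradw(NumericVector x, NumericVector gy,
                      IntegerVector stride, IntegerVector pad,
                      IntegerVector ksize) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4];
  int Ho = gd[0], Wo = gd[1], Do = gd[2], Cout = gd[3];
  int kh = ksize[0], kw = ksize[1], kd = ksize[2];
  int sh = stride[0], sw = stride[1], sd = stride[2];
  int ph = pad[0], pw = pad[1], pd = pad[2];
  size_t K = (size_t)kh * kw * kd * C, S = (size_t)Ho * Wo * Do;
  NumericVector gw(K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, kd, C, Cout);
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat col(K, S);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (size_t)n * H * W * D * C, H, W, D, C,
             kh, kw, kd, sh, sw, sd, ph, pw, pd, Ho, Wo, Do, col);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * S * Cout, S, Cout, false, true);
    GW += col * GY;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(GY.col(o));
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
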