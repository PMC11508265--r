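// im2col-based 2D convolution primitives (forward + backward) used by the
// native network engine.  Tensor layout throughout: column-major R arrays
//   feature maps  x : [H, W, C, N]
//   conv weights  w : [kh, kw, Cin, Cout]
//   deconv weights w: [kh, kw, Cout, Cin]
// so that reshaping to an (kh*kw*C) x P matrix is a zero-copy view and the
// GEMM result lands directly in the output array's memory order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflection without edge repetition: -1 -> 1, n -> n-2 (torch-style)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// pad_mode: 0 = zeros, 1 = reflect.
// Loops run with the output position p outermost and the kernel/channel
// index r innermost so that writes to col (and reads in col2im) are
// contiguous down each column; reads from X are short contiguous runs.
static void im2col(const arma::cube &X, int kh, int kw, int stride, int pad,
                   int pad_mode, int Ho, int Wo, arma::mat &col) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const std::size_t plane = (std::size_t)H * W;
  const double *x = X.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *dst = col.colptr(ho + Ho * wo);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const bool interior = h0 >= 0 && h0 + kh <= H && w0 >= 0 &&
                            w0 + kw <= W;
      if (interior) {
        for (int c = 0; c < C; ++c) {
          const double *xc = x + c * plane;
          for (int iw = 0; iw < kw; ++iw) {
            const double *src = xc + (std::size_t)(w0 + iw) * H + h0;
            for (int ih = 0; ih < kh; ++ih) *dst++ = src[ih];
          }
        }
      } else {
        for (int c = 0; c < C; ++c) {
          const double *xc = x + c * plane;
          for (int iw = 0; iw < kw; ++iw) {
            int wi = w0 + iw;
            bool w_in = (wi >= 0 && wi < W);
            if (!w_in && pad_mode == 1) { wi = reflect_idx(wi, W); w_in = true; }
            const double *src = xc + (std::size_t)(w_in ? wi : 0) * H;
            for (int ih = 0; ih < kh; ++ih) {
              int hi = h0 + ih;
              double v = 0.0;
              if (w_in) {
                if (hi >= 0 && hi < H) v = src[hi];
                else if (pad_mode == 1) v = src[reflect_idx(hi, H)];
              }
              *dst++ = v;
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat &col, int kh, int kw, int stride, int pad,
                   int pad_mode, int Ho, int Wo, arma::cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const std::size_t plane = (std::size_t)H * W;
  double *x = X.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *src = col.colptr(ho + Ho * wo);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const bool interior = h0 >= 0 && h0 + kh <= H && w0 >= 0 &&
                            w0 + kw <= W;
      if (interior) {
        for (int c = 0; c < C; ++c) {
          double *xc = x + c * plane;
          for (int iw = 0; iw < kw; ++iw) {
            double *dst = xc + (std::size_t)(w0 + iw) * H + h0;
            for (int ih = 0; ih < kh; ++ih) dst[ih] += *src++;
          }
        }
      } else {
        for (int c = 0; c < C; ++c) {
          double *xc = x + c * plane;
          for (int iw = 0; iw < kw; ++iw) {
            int wi = w0 + iw;
            bool w_in = (wi >= 0 && wi < W);
            if (!w_in && pad_mode == 1) { wi = reflect_idx(wi, W); w_in = true; }
            double *dst = xc + (std::size_t)(w_in ? wi : 0) * H;
            for (int ih = 0; ih < kh; ++ih) {
              int hi = h0 + ih;
              double v = *src++;
              if (!w_in) continue;
              if (hi < 0 || hi >= H) {
                if (pad_mode != 1) continue;
                hi = reflect_idx(hi, H);
              }
              dst[hi] += v;
            }
          }
        }
      }
    }
  }
}

static IntegerVector tensor_dim(const NumericVector &x, int ndim) {
  IntegerVector d = x.attr("dim");
  if (d.size() != ndim) stop("expected a %d-d array", ndim);
  return d;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int pad_mode) {
  IntegerVector xd = tensor_dim(x, 4), wd = tensor_dim(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int K = kh * kw * Cin, P = Ho * Wo;

  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    arma::cube Xn(const_cast<double *>(x.begin()) + (std::size_t)n * H * W * C,
                  H, W, C, false, true);
    im2col(Xn, kh, kw, stride, pad, pad_mode, Ho, Wo, col);
    arma::mat Yn(y.begin() + (std::size_t)n * P * Cout, P, Cout, false, true);
    Yn = col.t() * Wmat;
    if (b.size() == Cout) Yn.each_row() += arma::rowvec(b.begin(), Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int pad_mode, bool need_gx,
                    bool has_bias) {
  IntegerVector xd = tensor_dim(x, 4), wd = tensor_dim(w, 4),
                yd = tensor_dim(gy, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * Cin, P = Ho * Wo;

  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);

  arma::mat Wmat(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat col(K, P), gcol(K, P);
  arma::rowvec GB(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube Xn(const_cast<double *>(x.begin()) + (std::size_t)n * H * W * C,
                  H, W, C, false, true);
    arma::mat GYn(const_cast<double *>(gy.begin()) + (std::size_t)n * P * Cout,
                  P, Cout, false, true);
    im2col(Xn, kh, kw, stride, pad, pad_mode, Ho, Wo, col);
    GW += col * GYn;
    if (has_bias) GB += arma::sum(GYn, 0);
    if (need_gx) {
      gcol = Wmat * GYn.t();
      arma::cube GXn(gx.begin() + (std::size_t)n * H * W * C, H, W, C, false,
                     true);
      col2im(gcol, kh, kw, stride, pad, pad_mode, Ho, Wo, GXn);
    }
  }
  if (has_bias) std::copy(GB.begin(), GB.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed convolution, weight [kh, kw, Cout, Cin]
// [[Rcpp::export(name = ".cpp_convt2d_fwd")]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int pad, int outpad) {
  IntegerVector xd = tensor_dim(x, 4), wd = tensor_dim(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  if (Cin != C) stop("conv_transpose2d: input has %d channels, weight expects %d",
                     C, Cin);
  const int Ho = (H - 1) * stride - 2 * pad + kh + outpad;
  const int Wo = (W - 1) * stride - 2 * pad + kw + outpad;
  if (Ho <= 0 || Wo <= 0) stop("conv_transpose2d: non-positive output size");
  const int K = kh * kw * Cout, P = H * W;

  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double *>(w.begin()), K, Cin, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double *>(x.begin()) + (std::size_t)n * P * Cin, P,
                 Cin, false, true);
    col = Wmat * Xn.t();
    arma::cube Yn(y.begin() + (std::size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
                  false, true);
    // scatter kernel taps over the (Ho, Wo) canvas; grid positions are the
    // H x W input sites, i.e. col2im with input/output roles swapped
    col2im(col, kh, kw, stride, pad, 0, H, W, Yn);
    if (b.size() == Cout) {
      arma::mat Ym(y.begin() + (std::size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                   false, true);
      Ym.each_row() += arma::rowvec(b.begin(), Cout);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_convt2d_bwd")]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad, bool has_bias) {
  IntegerVector xd = tensor_dim(x, 4), wd = tensor_dim(w, 4),
                yd = tensor_dim(gy, 4);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * Cout, P = H * W;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);

  arma::mat Wmat(const_cast<double *>(w.begin()), K, Cin, false, true);
  arma::mat GW(gw.begin(), K, Cin, false, true);
  arma::mat gcol(K, P);
  arma::rowvec GB(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube GYn(const_cast<double *>(gy.begin()) +
                       (std::size_t)n * Ho * Wo * Cout,
                   Ho, Wo, Cout, false, true);
    im2col(GYn, kh, kw, stride, pad, 0, H, W, gcol);
    arma::mat Xn(const_cast<double *>(x.begin()) + (std::size_t)n * P * Cin, P,
                 Cin, false, true);
    arma::mat GXn(gx.begin() + (std::size_t)n * P * Cin, P, Cin, false, true);
    GXn = gcol.t() * Wmat;
    GW += gcol * Xn;
    if (has_bias) {
      arma::mat GYm(const_cast<double *>(gy.begin()) +
                        (std::size_t)n * Ho * Wo * Cout,
                    Ho * Wo, Cout, false, true);
      GB += arma::sum(GYm, 0);
    }
  }
  if (has_bias) std::copy(GB.begin(), GB.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
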