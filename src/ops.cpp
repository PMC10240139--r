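// Low-level tensor kernels for the multi-decoder U-Net.
//
// Tensor layout everywhere: column-major R arrays.
//   activations: (H, W, C, N)
//   conv weights: (kh, kw, Cin, Cout)   -- odd kernels, "same" zero padding
//   transposed-conv weights: (2, 2, Cin, Cout), stride 2
//
// Convolutions are im2col + GEMM so they ride on the BLAS R links against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& a, int& b, int& c, int& d) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("expected a 4-d array");
  a = xd[0]; b = xd[1]; c = xd[2]; d = xd[3];
}

// Fill Col (HW x kh*kw*C) for sample pointer xn; zero-padded borders.
static void im2col(const double* xn, int H, int W, int C, int kh, int kw,
                   arma::mat& Col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  Col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        double* colr = Col.colptr(r);
        const int hoff = dh - ph, woff = dw - pw;
        const int w0 = std::max(0, -woff), w1 = std::min(W, W - woff);
        const int h0 = std::max(0, -hoff), h1 = std::min(H, H - hoff);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w) {
          const double* src = xc + (size_t)(w + woff) * H + (h0 + hoff);
          std::copy(src, src + (h1 - h0), colr + (size_t)w * H + h0);
        }
      }
    }
  }
}

// Scatter-add the im2col adjoint back into dx for one sample.
static void col2im_acc(const arma::mat& dCol, int H, int W, int C, int kh, int kw,
                       double* dxn) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* dxc = dxn + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const double* colr = dCol.colptr(r);
        const int hoff = dh - ph, woff = dw - pw;
        const int w0 = std::max(0, -woff), w1 = std::min(W, W - woff);
        const int h0 = std::max(0, -hoff), h1 = std::min(H, H - hoff);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w) {
          double* dst = dxc + (size_t)(w + woff) * H + (h0 + hoff);
          const double* src = colr + (size_t)w * H + h0;
          for (int i = 0; i < h1 - h0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N); dims4(w, kh, kw, Cin, Cout);
  if (Cin != C) stop("conv2d: channel mismatch");
  const int HW = H * W, K = kh * kw * C;
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Col(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, Col);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = Col * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N); dims4(w, kh, kw, Cin, Cout);
  const int HW = H * W, K = kh * kw * C;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector dx((size_t)HW * C * N), dw((size_t)K * Cout), db(Cout);
  dx.attr("dim") = x.attr("dim");
  dw.attr("dim") = w.attr("dim");
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat Col(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, Col);
    arma::mat dY(dy.begin() + (size_t)n * HW * Cout, HW, Cout, false);
    dWm += Col.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dCol = dY * Wm.t();              // HW x K
    col2im_acc(dCol, H, W, C, kh, kw, dx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Reorder (2,2,Cin,Cout) weights into (Cin x 4*Cout) with column dh+2*dw+4*co.
static arma::mat tconv_wmat(const NumericVector& w, int Cin, int Cout) {
  arma::mat Wm2(Cin, 4 * Cout);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh)
          Wm2(ci, dh + 2 * dw + 4 * co) = wp[dh + 2 * dw + 4 * ((size_t)ci + (size_t)Cin * co)];
  return Wm2;
}

// [[Rcpp::export]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N); dims4(w, kh, kw, Cin, Cout);
  if (kh != 2 || kw != 2 || Cin != C) stop("convt2d: expects 2x2 kernel, matching channels");
  const int HW = H * W, Ho = 2 * H, Wo = 2 * W;
  arma::mat Wm2 = tconv_wmat(w, C, Cout);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C, false);
    arma::mat T = X * Wm2;                     // HW x 4*Cout
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)co * Ho * Wo;
      const double bc = b[co];
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          const double* t = T.colptr(dh + 2 * dw + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            double* dst = yc + (size_t)(2 * w2 + dw) * Ho + dh;
            const double* src = t + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + bc;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N, kh, kw, Cin, Cout;
  dims4(x, H, W, C, N); dims4(w, kh, kw, Cin, Cout);
  const int HW = H * W, Ho = 2 * H, Wo = 2 * W;
  arma::mat Wm2 = tconv_wmat(w, C, Cout);
  NumericVector dx((size_t)HW * C * N), dw_((size_t)4 * C * Cout), db(Cout);
  dx.attr("dim") = x.attr("dim");
  dw_.attr("dim") = w.attr("dim");
  arma::mat dWm2(C, 4 * Cout, arma::fill::zeros);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat dT(HW, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)co * Ho * Wo;
      double acc = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) acc += dyc[i];
      dbv[co] += acc;
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          double* t = dT.colptr(dh + 2 * dw + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            const double* src = dyc + (size_t)(2 * w2 + dw) * Ho + dh;
            double* dst = t + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dst[h] = src[2 * h];
          }
        }
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C, false);
    arma::mat dX(dx.begin() + (size_t)n * HW * C, HW, C, false, true);
    dX = dT * Wm2.t();
    dWm2 += X.t() * dT;
  }
  double* dwp = dw_.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh)
          dwp[dh + 2 * dw + 4 * ((size_t)ci + (size_t)C * co)] = dWm2(ci, dh + 2 * dw + 4 * co);
  return List::create(_["dx"] = dx, _["dw"] = dw_, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0..3 = dh + 2*dw
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)C * n) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const double v = xc[(size_t)(2 * w + dw) * H + 2 * h + dh];
              if (v > best) { best = v; bi = dh + 2 * dw; }
            }
          y[o] = best; idx[o] = bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx, int H, int W) {
  int Ho, Wo, C, N;
  dims4(dy, Ho, Wo, C, N);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)(c + (size_t)C * n) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          const int dh = idx[o] % 2, dw = idx[o] / 2;
          dxc[(size_t)(2 * w + dw) * H + 2 * h + dh] += dy[o];
        }
    }
  return dx;
}

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double m = s / (HW * N);
    mean[c] = m;
    var[c] = s2 / (HW * N) - m * m;   // population variance
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
                           NumericVector mean, NumericVector invstd) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y((size_t)HW * C * N);
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * invstd[c];
      const double b0 = beta[c] - a * mean[c];
      const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      double* yc = y.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b0;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector gamma, NumericVector mean,
               NumericVector invstd, NumericVector dy) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx((size_t)HW * C * N), dgamma(C), dbeta(C);
  dx.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyxh = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      const double* dyc = dy.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mean[c]) * invstd[c];
        sdy += dyc[i];
        sdyxh += dyc[i] * xh;
      }
    }
    dgamma[c] = sdyxh; dbeta[c] = sdy;
    const double a = gamma[c] * invstd[c] / M;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      const double* dyc = dy.begin() + ((size_t)c + (size_t)C * n) * HW;
      double* dxc = dx.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mean[c]) * invstd[c];
        dxc[i] = a * (M * dyc[i] - sdy - xh * sdyxh);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(clone(x));
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector x, NumericVector dy) {
  NumericVector dx(clone(dy));
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (x[i] <= 0) dx[i] = 0;
  return dx;
}

// Catmull-Rom cubic kernel (a = -0.5), the common "bicubic" choice.
static inline double cubic_kernel(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t < 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bicubic(NumericVector img, int outH, int outW) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  NumericVector out((size_t)outH * outW * C);
  if (d.size() > 2) out.attr("dim") = IntegerVector::create(outH, outW, C);
  else out.attr("dim") = IntegerVector::create(outH, outW);
  const double sh = (double)H / outH, sw = (double)W / outW;
  // precompute row taps
  std::vector<int> hi(outH * 4);
  std::vector<double> hw(outH * 4);
  for (int i = 0; i < outH; ++i) {
    const double src = (i + 0.5) * sh - 0.5;
    const int i0 = (int)std::floor(src) - 1;
    for (int k = 0; k < 4; ++k) {
      int ii = std::min(std::max(i0 + k, 0), H - 1);
      hi[4 * i + k] = ii;
      hw[4 * i + k] = cubic_kernel(src - (i0 + k));
    }
  }
  for (int c = 0; c < C; ++c) {
    const double* ic = img.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * outH * outW;
    for (int j = 0; j < outW; ++j) {
      const double src = (j + 0.5) * sw - 0.5;
      const int j0 = (int)std::floor(src) - 1;
      int ji[4]; double jw[4];
      for (int k = 0; k < 4; ++k) {
        ji[k] = std::min(std::max(j0 + k, 0), W - 1);
        jw[k] = cubic_kernel(src - (j0 + k));
      }
      for (int i = 0; i < outH; ++i) {
        double v = 0;
        for (int kj = 0; kj < 4; ++kj) {
          double rv = 0;
          const double* col = ic + (size_t)ji[kj] * H;
          for (int ki = 0; ki < 4; ++ki) rv += hw[4 * i + ki] * col[hi[4 * i + ki]];
          v += jw[kj] * rv;
        }
        oc[(size_t)j * outH + i] = v;
      }
    }
  }
  return out;
}
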