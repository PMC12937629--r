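// Convolution, depthwise convolution and batch-normalisation kernels.
//
// Tensor convention throughout: R arrays with dim = c(H, W, C, N)
// (height fastest, column-major).  Standard convolutions are computed as
// im2col followed by a BLAS GEMM; depthwise convolutions and batch-norm
// reductions are direct loops (they are memory-bound, not compute-bound).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// cols: (k*k*C) x (Ho*Wo); row index = kh + k*kw + k*k*c, col = oh + Ho*ow.
// Row ordering matches an R weight array of dim c(k, k, Cin, Cout) flattened
// over its first three dimensions. Out-of-image taps are zero (zero padding).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      double* cj = cols.colptr((size_t)oh + (size_t)Ho * ow);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int iw = ow * stride + kw - pad;
          bool win = (iw >= 0 && iw < W);
          for (int kh = 0; kh < k; ++kh) {
            int ih = oh * stride + kh - pad;
            int r = kh + k * (kw + k * c);
            cj[r] = (win && ih >= 0 && ih < H) ? xc[ih + (size_t)H * iw] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, double* dx, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double* cj = cols.colptr((size_t)oh + (size_t)Ho * ow);
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)H * iw] += cj[kh + k * (kw + k * c)];
          }
        }
      }
    }
  }
}

static inline int out_dim(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: input has %d channels, weights expect %d", C, Cin);
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  arma::mat cols;
  if (!pointwise) cols.set_size((size_t)k * k * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    if (pointwise) {
      // 1x1 stride-1 convolution is a plain channel-mixing GEMM
      arma::mat X(x.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                  false, true);
      Y = X * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, cols);
      Y = cols.t() * Wm;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)k * k * Cin * Cout);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
  bool pointwise = (k == 1 && stride == 1 && pad == 0);
  arma::mat cols;
  if (!pointwise) cols.set_size((size_t)k * k * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(dy.begin() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    if (pointwise) {
      arma::mat X(x.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                  false, true);
      arma::mat dX(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                   false, true);
      dWm += X.t() * dY;
      dX = dY * Wm.t();
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, cols);
      dWm += cols * dY;
      arma::mat dcols = Wm * dY.t();
      col2im_acc(dcols, dx.begin() + (size_t)H * W * C * n,
                 H, W, C, k, stride, pad, Ho, Wo);
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Depthwise convolution: one k x k spatial filter per channel,
// weights dim = c(k, k, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  if (wd[2] != C) stop("dwconv: channel mismatch");
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = 0.0;
          for (int kw = 0; kw < k; ++kw) {
            int iw = ow * stride + kw - pad;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = oh * stride + kh - pad;
              if (ih < 0 || ih >= H) continue;
              acc += xc[ih + (size_t)H * iw] * wc[kh + k * kw];
            }
          }
          yc[oh + (size_t)Ho * ow] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)k * k * c;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double g = dyc[oh + (size_t)Ho * ow];
          if (g == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            int iw = ow * stride + kw - pad;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = oh * stride + kh - pad;
              if (ih < 0 || ih >= H) continue;
              dxc[ih + (size_t)H * iw] += g * wc[kh + k * kw];
              dwc[kh + k * kw] += g * xc[ih + (size_t)H * iw];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Batch norm over (H, W, N) per channel.  Variance is the biased
// (population) estimate, as used for the normalisation itself.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  double m = (double)H * W * N;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// Affine normalisation, optionally fused with ReLU.
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mu,
                           NumericVector var, double eps, bool relu) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)x.size());
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv, b = beta[c] - gamma[c] * inv * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      if (relu) {
        for (size_t i = 0; i < (size_t)H * W; ++i) {
          double v = a * xc[i] + b;
          yc[i] = v > 0.0 ? v : 0.0;
        }
      } else {
        for (size_t i = 0; i < (size_t)H * W; ++i) yc[i] = a * xc[i] + b;
      }
    }
  }
  y.attr("dim") = xd;
  return y;
}

// Gradient through ReLU given the cached ReLU output y.
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx((R_xlen_t)dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0.0 ? dy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// y = relu(a + b), elementwise over equal-shape arrays.
// [[Rcpp::export]]
NumericVector cpp_add_relu(NumericVector a, NumericVector b) {
  NumericVector y((R_xlen_t)a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    double v = a[i] + b[i];
    y[i] = v > 0.0 ? v : 0.0;
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  double m = (double)H * W * N;
  NumericVector dx((R_xlen_t)x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        double xh = (xc[i] - mu[c]) * inv;
        sdy += dyc[i];
        sdyx += dyc[i] * xh;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double mdy = sdy / m, mdyx = sdyx / m, g = gamma[c] * inv;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        double xh = (xc[i] - mu[c]) * inv;
        dxc[i] = g * (dyc[i] - mdy - xh * mdyx);
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
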