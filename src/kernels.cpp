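// Dense numerical kernels for the network layers.
// Feature maps are R arrays laid out (H, W, C, N), column-major, H fastest.
// Convolution weights are (k, k, C_in/groups, C_out).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N), got %d dims", (int)d.size());
  return d;
}

// im2col for one sample / one group: out K x (Ho*Wo), K = k*k*Cg,
// row index = kh + k*kw + k*k*c, col index = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C, int n,
                   int g, int Cg, int k, int stride, int pad,
                   int Ho, int Wo, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < Cg; ++c) {
    int cin = g * Cg + c;
    const double* xc = x + (size_t)H * W * (cin + (size_t)C * n);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          const double* col = xc + (size_t)H * iw;
          double* mrow = M.memptr() + row + (size_t)M.n_rows * Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + kh;
            if (ih >= 0 && ih < H) mrow[(size_t)M.n_rows * ho] = col[ih];
          }
        }
      }
    }
  }
}

static void col2im_acc(double* dx, int H, int W, int C, int n,
                       int g, int Cg, int k, int stride, int pad,
                       int Ho, int Wo, const arma::mat& dM) {
  for (int c = 0; c < Cg; ++c) {
    int cin = g * Cg + c;
    double* xc = dx + (size_t)H * W * (cin + (size_t)C * n);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          double* col = xc + (size_t)H * iw;
          const double* mrow = dM.memptr() + row + (size_t)dM.n_rows * Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + kh;
            if (ih >= 0 && ih < H) col[ih] += mrow[(size_t)dM.n_rows * ho];
          }
        }
      }
    }
  }
}

// Direct (loop) convolution for small kernels-times-channels; avoids the
// im2col scratch matrix, which dominates for depthwise and narrow layers.
static void conv_direct_fwd(const double* x, const double* w, double* y,
                            int H, int W, int C, int N, int k, int Cg,
                            int Cout, int stride, int pad, int Ho, int Wo,
                            int groups) {
  int Og = Cout / groups;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      int g = co / Og;
      double* yp = y + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int c = 0; c < Cg; ++c) {
        int cin = g * Cg + c;
        const double* xp = x + (size_t)H * W * (cin + (size_t)C * n);
        const double* wp = w + (size_t)k * k * (c + (size_t)Cg * co);
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            double wv = wp[kh + k * kw];
            if (wv == 0.0) continue;
            int ho0 = std::max(0, (pad - kh + stride - 1) / stride);
            int ho1 = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
            for (int wo = 0; wo < Wo; ++wo) {
              int iw = wo * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              const double* xc = xp + (size_t)H * iw - pad + kh;
              double* yc = yp + (size_t)Ho * wo;
              if (stride == 1) {
                for (int ho = ho0; ho < ho1; ++ho) yc[ho] += wv * xc[ho];
              } else {
                for (int ho = ho0; ho < ho1; ++ho) yc[ho] += wv * xc[ho * stride];
              }
            }
          }
      }
    }
}

static void conv_direct_bwd(const double* x, const double* w, const double* dy,
                            double* dx, double* dw,
                            int H, int W, int C, int N, int k, int Cg,
                            int Cout, int stride, int pad, int Ho, int Wo,
                            int groups) {
  int Og = Cout / groups;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      int g = co / Og;
      const double* dyp = dy + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int c = 0; c < Cg; ++c) {
        int cin = g * Cg + c;
        const double* xp = x + (size_t)H * W * (cin + (size_t)C * n);
        double* dxp = dx + (size_t)H * W * (cin + (size_t)C * n);
        const double* wp = w + (size_t)k * k * (c + (size_t)Cg * co);
        double* dwp = dw + (size_t)k * k * (c + (size_t)Cg * co);
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            double wv = wp[kh + k * kw];
            double acc = 0.0;
            int ho0 = std::max(0, (pad - kh + stride - 1) / stride);
            int ho1 = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
            for (int wo = 0; wo < Wo; ++wo) {
              int iw = wo * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              const double* xc = xp + (size_t)H * iw - pad + kh;
              double* dxc = dxp + (size_t)H * iw - pad + kh;
              const double* dyc = dyp + (size_t)Ho * wo;
              if (stride == 1) {
                for (int ho = ho0; ho < ho1; ++ho) {
                  acc += dyc[ho] * xc[ho];
                  dxc[ho] += wv * dyc[ho];
                }
              } else {
                for (int ho = ho0; ho < ho1; ++ho) {
                  acc += dyc[ho] * xc[ho * stride];
                  dxc[ho * stride] += wv * dyc[ho];
                }
              }
            }
            dwp[kh + k * kw] += acc;
          }
      }
    }
}

// Use direct loops when the per-output-channel reduction is small (depthwise
// or narrow layers); im2col + GEMM pays off only for wide dense convs.
static bool use_direct(int k, int Cg) { return k > 1 && Cg * k * k <= 512; }

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cg * groups) stop("conv input channels %d incompatible with weight %d x %d groups", C, Cg, groups);
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  int Og = Cout / groups, K = k * k * Cg;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv output collapsed to zero size");
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wfull(const_cast<double*>(w.begin()), K, Cout, false, true);
  bool has_bias = bias.size() > 0;

  if (k == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * (g * Cg + (size_t)C * n),
                           (size_t)H * W, Cg, false, true);
        arma::mat Y = Xn * Wfull.cols(g * Og, g * Og + Og - 1);
        std::memcpy(out.begin() + (size_t)Ho * Wo * (g * Og + (size_t)Cout * n),
                    Y.memptr(), sizeof(double) * Y.n_elem);
      }
    }
  } else if (use_direct(k, Cg)) {
    conv_direct_fwd(x.begin(), w.begin(), out.begin(), H, W, C, N, k, Cg,
                    Cout, stride, pad, Ho, Wo, groups);
  } else {
    arma::mat M(K, (size_t)Ho * Wo);
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        im2col(x.begin(), H, W, C, n, g, Cg, k, stride, pad, Ho, Wo, M);
        arma::mat Y = M.t() * Wfull.cols(g * Og, g * Og + Og - 1);
        std::memcpy(out.begin() + (size_t)Ho * Wo * (g * Og + (size_t)Cout * n),
                    Y.memptr(), sizeof(double) * Y.n_elem);
      }
    }
  }
  if (has_bias) {
    double* o = out.begin();
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double bv = bias[co];
        double* p = o + (size_t)Ho * Wo * (co + (size_t)Cout * n);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) p[i] += bv;
      }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int groups, bool need_bias) {
  IntegerVector xd = dims4(x), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cg = wd[2];
  int Og = Cout / groups, K = k * k * Cg;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  const arma::mat Wfull(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWfull(dw.begin(), K, Cout, false, true);

  if (k == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * (g * Cg + (size_t)C * n),
                           (size_t)H * W, Cg, false, true);
        const arma::mat Dy(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * (g * Og + (size_t)Cout * n),
                           (size_t)Ho * Wo, Og, false, true);
        arma::mat dXn(dx.begin() + (size_t)H * W * (g * Cg + (size_t)C * n),
                      (size_t)H * W, Cg, false, true);
        dXn += Dy * Wfull.cols(g * Og, g * Og + Og - 1).t();
        dWfull.cols(g * Og, g * Og + Og - 1) += Xn.t() * Dy;
      }
    }
  } else if (use_direct(k, Cg)) {
    conv_direct_bwd(x.begin(), w.begin(), dy.begin(), dx.begin(), dw.begin(),
                    H, W, C, N, k, Cg, Cout, stride, pad, Ho, Wo, groups);
  } else {
    arma::mat M(K, (size_t)Ho * Wo);
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        im2col(x.begin(), H, W, C, n, g, Cg, k, stride, pad, Ho, Wo, M);
        const arma::mat Dy(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * (g * Og + (size_t)Cout * n),
                           (size_t)Ho * Wo, Og, false, true);
        dWfull.cols(g * Og, g * Og + Og - 1) += M * Dy;
        arma::mat dM = Wfull.cols(g * Og, g * Og + Og - 1) * Dy.t();
        col2im_acc(dx.begin(), H, W, C, n, g, Cg, k, stride, pad, Ho, Wo, dM);
      }
    }
  }

  NumericVector db;
  if (need_bias) {
    db = NumericVector(Cout);
    const double* p = dy.begin();
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double s = 0.0;
        const double* q = p + (size_t)Ho * Wo * (co + (size_t)Cout * n);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += q[i];
        db[co] += s;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Fused hard-swish: y = v * clamp(v + 3, 0, 6) / 6.
// [[Rcpp::export]]
NumericVector hswish_fwd_cpp(NumericVector v) {
  NumericVector y(no_init(v.size()));
  y.attr("dim") = v.attr("dim");
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    double t = v[i] + 3.0;
    if (t < 0) t = 0; else if (t > 6) t = 6;
    y[i] = v[i] * t / 6.0;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector hswish_bwd_cpp(NumericVector v, NumericVector dy) {
  NumericVector dx(no_init(v.size()));
  dx.attr("dim") = v.attr("dim");
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    double d;
    if (v[i] <= -3.0) d = 0.0;
    else if (v[i] >= 3.0) d = 1.0;
    else d = (2.0 * v[i] + 3.0) / 6.0;
    dx[i] = dy[i] * d;
  }
  return dx;
}

// y = x * g where each dim of g equals the matching dim of x or 1.
// [[Rcpp::export]]
NumericVector bcast_mul_fwd_cpp(NumericVector x, NumericVector g) {
  IntegerVector xd = dims4(x), gd = dims4(g);
  size_t sh[4], st = 1;
  for (int ax = 0; ax < 4; ++ax) {
    if (gd[ax] != xd[ax] && gd[ax] != 1) stop("broadcast dim mismatch");
    sh[ax] = (gd[ax] == 1) ? 0 : st;
    st *= gd[ax];
  }
  NumericVector y(no_init(x.size()));
  y.attr("dim") = xd;
  size_t i = 0;
  for (int n = 0; n < xd[3]; ++n)
    for (int c = 0; c < xd[2]; ++c)
      for (int w = 0; w < xd[1]; ++w) {
        size_t base = n * sh[3] + c * sh[2] + w * sh[1];
        if (sh[0] == 0) {
          double gv = g[base];
          for (int h = 0; h < xd[0]; ++h, ++i) y[i] = x[i] * gv;
        } else {
          for (int h = 0; h < xd[0]; ++h, ++i) y[i] = x[i] * g[base + h * sh[0]];
        }
      }
  return y;
}

// Gradients of the broadcast product: dx = dy .* g (expanded),
// dg = sum over broadcast axes of dy .* x.
// [[Rcpp::export]]
List bcast_mul_bwd_cpp(NumericVector x, NumericVector g, NumericVector dy) {
  IntegerVector xd = dims4(x), gd = dims4(g);
  size_t sh[4], st = 1;
  for (int ax = 0; ax < 4; ++ax) {
    sh[ax] = (gd[ax] == 1) ? 0 : st;
    st *= gd[ax];
  }
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = xd;
  NumericVector dg(g.size());
  dg.attr("dim") = gd;
  size_t i = 0;
  for (int n = 0; n < xd[3]; ++n)
    for (int c = 0; c < xd[2]; ++c)
      for (int w = 0; w < xd[1]; ++w) {
        size_t base = n * sh[3] + c * sh[2] + w * sh[1];
        if (sh[0] == 0) {
          double gv = g[base], acc = 0.0;
          for (int h = 0; h < xd[0]; ++h, ++i) {
            dx[i] = dy[i] * gv;
            acc += dy[i] * x[i];
          }
          dg[base] += acc;
        } else {
          for (int h = 0; h < xd[0]; ++h, ++i) {
            size_t gi = base + h * sh[0];
            dx[i] = dy[i] * g[gi];
            dg[gi] += dy[i] * x[i];
          }
        }
      }
  return List::create(_["dx"] = dx, _["dg"] = dg);
}

// Per-channel mean and (biased) variance over H, W, N.
// [[Rcpp::export]]
List bn_moments_cpp(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = (double)plane * N;
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                         NumericVector mean, NumericVector var, double eps) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv, b = beta[c] - gamma[c] * mean[c] * inv;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) q[i] = a * p[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector var, double eps, bool batch_stats) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + plane * (c + (size_t)C * n);
      const double* pd = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - mean[c]) * inv;
        sum_dy += pd[i];
        sum_dy_xhat += pd[i] * xh;
      }
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    double g = gamma[c] * inv;
    double mu_dy = sum_dy / m, mu_dy_xhat = sum_dy_xhat / m;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + plane * (c + (size_t)C * n);
      const double* pd = dy.begin() + plane * (c + (size_t)C * n);
      double* pq = dx.begin() + plane * (c + (size_t)C * n);
      if (batch_stats) {
        for (size_t i = 0; i < plane; ++i) {
          double xh = (px[i] - mean[c]) * inv;
          pq[i] = g * (pd[i] - mu_dy - xh * mu_dy_xhat);
        }
      } else {
        for (size_t i = 0; i < plane; ++i) pq[i] = g * pd[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
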