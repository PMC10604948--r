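// Low-level dense-prediction primitives used by the stacked FCN.
//
// Tensor layout everywhere: feature maps are R arrays dim (H, W, C, B),
// column-major, so a per-sample channel plane is contiguous and a per-sample
// (H*W x C) matrix view needs no copy.  Convolution weights are (k, k, Cin,
// Cout); flattening the first three dims column-major gives the GEMM weight
// matrix (k*k*Cin x Cout) directly.  All convolutions are stride 1 with
// "same" zero padding; kernels are odd-sized.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat view(double* p, arma::uword r, arma::uword c) {
  return arma::mat(p, r, c, false, true);
}

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v(R_xlen_t((size_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make4i(int a, int b, int c, int d) {
  IntegerVector v(R_xlen_t((size_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill COL (HW x k*k*Cin) for one sample slice x (H x W x Cin).
// COL column index r = kh + k*kw + k*k*cin; pixel index = y + H*x.
// The GEMM path normally runs in single precision (well inside float range;
// the optimiser adds its own noise floor); `dbl = true` switches to double
// for verification against finite differences.
template <typename MAT>
static void im2col(const double* x, int H, int W, int Cin, int k, int dil,
                   MAT& COL) {
  typedef typename MAT::elem_type T;
  const int c0 = (k - 1) / 2;
  const int HW = H * W;
  COL.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    const double* plane = x + (size_t)cin * HW;
    for (int kw = 0; kw < k; ++kw) {
      const int dx = (kw - c0) * dil;
      for (int kh = 0; kh < k; ++kh) {
        const int dy = (kh - c0) * dil;
        T* col = COL.colptr(kh + k * kw + k * k * cin);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int xo = x0; xo < x1; ++xo) {
          const double* src = plane + (size_t)(xo + dx) * H + (y0 + dy);
          T* dst = col + (size_t)xo * H + y0;
          for (int i = 0; i < y1 - y0; ++i) dst[i] = (T)src[i];
        }
      }
    }
  }
}

// Scatter-add transpose of im2col: GCOL (HW x k*k*Cin) into gx slice.
template <typename MAT>
static void col2im(const MAT& GCOL, int H, int W, int Cin, int k,
                   int dil, double* gx) {
  typedef typename MAT::elem_type T;
  const int c0 = (k - 1) / 2;
  const int HW = H * W;
  for (int cin = 0; cin < Cin; ++cin) {
    double* plane = gx + (size_t)cin * HW;
    for (int kw = 0; kw < k; ++kw) {
      const int dx = (kw - c0) * dil;
      for (int kh = 0; kh < k; ++kh) {
        const int dy = (kh - c0) * dil;
        const T* col = GCOL.colptr(kh + k * kw + k * k * cin);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int xo = x0; xo < x1; ++xo) {
          double* dst = plane + (size_t)(xo + dx) * H + (y0 + dy);
          const T* src = col + (size_t)xo * H + y0;
          for (int i = 0; i < y1 - y0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

template <typename MAT>
static void conv_fwd_impl(const NumericVector& x, const NumericVector& w,
                          const NumericVector& bias, int dilation,
                          NumericVector& y, int H, int W, int Cin, int B,
                          int k, int Cout) {
  typedef typename MAT::elem_type T;
  const int HW = H * W, K2C = k * k * Cin;
  MAT Wm(K2C, Cout);
  for (int i = 0; i < K2C * Cout; ++i) Wm[i] = (T)w[i];
  MAT COL(HW, K2C), Y(HW, Cout);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * HW * Cin, H, W, Cin, k, dilation, COL);
    Y = COL * Wm;
    double* yb = y.begin() + (size_t)b * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const T* src = Y.colptr(co);
      const double bc = bias[co % bias.size()];
      double* dst = yb + (size_t)co * HW;
      for (int i = 0; i < HW; ++i) dst[i] = (double)src[i] + bc;
    }
  }
}

template <typename MAT>
static void conv_bwd_impl(const NumericVector& x, const NumericVector& w,
                          const NumericVector& gy, int dilation,
                          NumericVector& gx, NumericVector& gw,
                          NumericVector& gb, int H, int W, int Cin, int B,
                          int k, int Cout) {
  typedef typename MAT::elem_type T;
  const int HW = H * W, K2C = k * k * Cin;
  MAT Wm(K2C, Cout);
  for (int i = 0; i < K2C * Cout; ++i) Wm[i] = (T)w[i];
  MAT GWa(K2C, Cout, arma::fill::zeros);
  MAT COL(HW, K2C), GCOL(HW, K2C), GY(HW, Cout);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * HW * Cin, H, W, Cin, k, dilation, COL);
    const double* gyb = gy.begin() + (size_t)b * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      T* dst = GY.colptr(co);
      const double* src = gyb + (size_t)co * HW;
      double acc = 0;
      for (int i = 0; i < HW; ++i) { dst[i] = (T)src[i]; acc += src[i]; }
      gb[co] += acc;
    }
    GWa += COL.t() * GY;
    GCOL = GY * Wm.t();
    col2im(GCOL, H, W, Cin, k, dilation, gx.begin() + (size_t)b * HW * Cin);
  }
  for (int i = 0; i < K2C * Cout; ++i) gw[i] = (double)GWa[i];
}

static IntegerVector tdim(SEXP a) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(a, R_DimSymbol));
  return d;
}

// [[Rcpp::export(name = ".cm_conv2d_fwd")]]
NumericVector cm_conv2d_fwd(NumericVector x, NumericVector w,
                            NumericVector bias, int dilation,
                            bool dbl = false) {
  IntegerVector dx = tdim(x), dw = tdim(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight/input channel mismatch");
  NumericVector y = make4(H, W, Cout, B);
  if (dbl)
    conv_fwd_impl<arma::mat>(x, w, bias, dilation, y, H, W, Cin, B, k, Cout);
  else
    conv_fwd_impl<arma::fmat>(x, w, bias, dilation, y, H, W, Cin, B, k, Cout);
  return y;
}

// [[Rcpp::export(name = ".cm_conv2d_bwd")]]
List cm_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int dilation, bool dbl = false) {
  IntegerVector dx = tdim(x), dw = tdim(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  const int k = dw[0], Cout = dw[3];
  NumericVector gx = make4(H, W, Cin, B);
  NumericVector gw = make4(k, k, Cin, Cout);
  NumericVector gb(Cout);
  if (dbl)
    conv_bwd_impl<arma::mat>(x, w, gy, dilation, gx, gw, gb, H, W, Cin, B,
                             k, Cout);
  else
    conv_bwd_impl<arma::fmat>(x, w, gy, dilation, gx, gw, gb, H, W, Cin, B,
                              k, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2, stride 2: exact upsampling-by-2.
// [[Rcpp::export(name = ".cm_convt2_fwd")]]
NumericVector cm_convt2_fwd(NumericVector x, NumericVector w,
                            NumericVector bias) {
  IntegerVector dx = tdim(x), dw = tdim(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  const int Cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Cin) stop("convt weight mismatch");
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;
  NumericVector y = make4(H2, W2, Cout, B);
  arma::mat Yp(HW, Cout);
  for (int b = 0; b < B; ++b) {
    arma::mat X = view((double*)x.begin() + (size_t)b * HW * Cin, HW, Cin);
    double* ybase = y.begin() + (size_t)b * H2 * W2 * Cout;
    for (int dh = 0; dh < 2; ++dh) {
      for (int dwid = 0; dwid < 2; ++dwid) {
        arma::mat Ws(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Ws(ci, co) = w[dh + 2 * dwid + 4 * ci + 4 * Cin * co];
        Yp = X * Ws;
        for (int co = 0; co < Cout; ++co) {
          double* pl = ybase + (size_t)co * H2 * W2;
          const double bco = bias[co];
          for (int xo = 0; xo < W; ++xo) {
            const double* src = Yp.colptr(co) + (size_t)xo * H;
            double* dst = pl + (size_t)(2 * xo + dwid) * H2 + dh;
            for (int yo = 0; yo < H; ++yo) dst[2 * yo] = src[yo] + bco;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cm_convt2_bwd")]]
List cm_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = tdim(x), dw = tdim(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  const int Cout = dw[3];
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;
  NumericVector gx = make4(H, W, Cin, B);
  NumericVector gw = make4(2, 2, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat GYp(HW, Cout);
  for (int b = 0; b < B; ++b) {
    arma::mat X = view((double*)x.begin() + (size_t)b * HW * Cin, HW, Cin);
    arma::mat GX = view(gx.begin() + (size_t)b * HW * Cin, HW, Cin);
    const double* gybase = gy.begin() + (size_t)b * H2 * W2 * Cout;
    for (int dh = 0; dh < 2; ++dh) {
      for (int dwid = 0; dwid < 2; ++dwid) {
        for (int co = 0; co < Cout; ++co) {
          const double* pl = gybase + (size_t)co * H2 * W2;
          double* dst = GYp.colptr(co);
          double acc = 0.0;
          for (int xo = 0; xo < W; ++xo) {
            const double* src = pl + (size_t)(2 * xo + dwid) * H2 + dh;
            double* d2 = dst + (size_t)xo * H;
            for (int yo = 0; yo < H; ++yo) { d2[yo] = src[2 * yo]; }
          }
          (void)acc;
        }
        arma::mat Ws(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Ws(ci, co) = w[dh + 2 * dwid + 4 * ci + 4 * Cin * co];
        GX += GYp * Ws.t();
        arma::mat GWs = X.t() * GYp;  // Cin x Cout
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            gw[dh + 2 * dwid + 4 * ci + 4 * Cin * co] += GWs(ci, co);
      }
    }
  }
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* pl = gy.begin() + (size_t)b * H2 * W2 * Cout +
                         (size_t)co * H2 * W2;
      for (int i = 0; i < H2 * W2; ++i) acc += pl[i];
    }
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cm_maxpool2_fwd")]]
List cm_maxpool2_fwd(NumericVector x) {
  IntegerVector dx = tdim(x);
  const int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, B);
  IntegerVector idx = make4i(Ho, Wo, C, B);
  size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* pl = x.begin() + ((size_t)b * C + c) * H * W;
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          int best = 2 * yo + H * (2 * xo);
          double bv = pl[best];
          const int cand[3] = {2 * yo + 1 + H * (2 * xo),
                               2 * yo + H * (2 * xo + 1),
                               2 * yo + 1 + H * (2 * xo + 1)};
          for (int t = 0; t < 3; ++t)
            if (pl[cand[t]] > bv) { bv = pl[cand[t]]; best = cand[t]; }
          // layout of y is (Ho, Wo, C, B): yo fastest
          size_t oi = (size_t)yo + (size_t)Ho * xo +
                      (size_t)Ho * Wo * ((size_t)b * C + c);
          y[oi] = bv;
          idx[oi] = best;
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cm_maxpool2_bwd")]]
NumericVector cm_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H,
                              int W) {
  IntegerVector dg = tdim(gy);
  const int Ho = dg[0], Wo = dg[1], C = dg[2], B = dg[3];
  NumericVector gx = make4(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* pl = gx.begin() + ((size_t)b * C + c) * H * W;
      const size_t base = (size_t)Ho * Wo * ((size_t)b * C + c);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        pl[idx[base + i]] += gy[base + i];
    }
  return gx;
}

// f x f average pooling (used for the multi-scale input pyramid).
// [[Rcpp::export(name = ".cm_avgpool_fwd")]]
NumericVector cm_avgpool_fwd(NumericVector x, int f) {
  IntegerVector dx = tdim(x);
  const int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  if (H % f || W % f) stop("avgpool needs dims divisible by factor");
  const int Ho = H / f, Wo = W / f;
  NumericVector y = make4(Ho, Wo, C, B);
  const double inv = 1.0 / (f * f);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* pl = x.begin() + ((size_t)b * C + c) * H * W;
      double* po = y.begin() + ((size_t)b * C + c) * Ho * Wo;
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          double acc = 0.0;
          for (int dx2 = 0; dx2 < f; ++dx2) {
            const double* col = pl + (size_t)(xo * f + dx2) * H + yo * f;
            for (int dy = 0; dy < f; ++dy) acc += col[dy];
          }
          po[yo + (size_t)Ho * xo] = acc * inv;
        }
    }
  return y;
}

// ---- batch-norm / activation / softmax helpers (hot path) -----------------

// per-channel mean and (biased) variance over (H, W, B)
// [[Rcpp::export(name = ".cm_bn_stats")]]
List cm_bn_stats(NumericVector x) {
  IntegerVector d = tdim(x);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + ((size_t)b * C + c) * HW;
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / ((double)HW * B);
    mean[c] = m;
    double v = s2 / ((double)HW * B) - m * m;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * sc[c] + sh[c], optionally ReLU-clamped at 0
// [[Rcpp::export(name = ".cm_scale_shift")]]
NumericVector cm_scale_shift(NumericVector x, NumericVector sc,
                             NumericVector sh, bool relu) {
  IntegerVector d = tdim(x);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector y = make4(d[0], d[1], C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)b * C + c) * HW;
      double* q = y.begin() + ((size_t)b * C + c) * HW;
      const double a = sc[c], t = sh[c];
      if (relu)
        for (int i = 0; i < HW; ++i) {
          double v = p[i] * a + t;
          q[i] = v > 0 ? v : 0;
        }
      else
        for (int i = 0; i < HW; ++i) q[i] = p[i] * a + t;
    }
  return y;
}

// per-channel sums of g and g * xhat (for dbeta / dgamma), where the ReLU
// mask is taken from y (> 0) first; returns the masked g as well.
// [[Rcpp::export(name = ".cm_bn_relu_bwd1")]]
List cm_bn_relu_bwd1(NumericVector gy, NumericVector y, NumericVector xhat,
                     bool relu) {
  IntegerVector d = tdim(gy);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector g = make4(d[0], d[1], C, B);
  NumericVector dbeta(C), dgamma(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)b * C + c) * HW;
      const double* pg = gy.begin() + off;
      const double* py = y.begin() + off;
      const double* px = xhat.begin() + off;
      double* pm = g.begin() + off;
      double sb = 0, sg = 0;
      for (int i = 0; i < HW; ++i) {
        double v = (!relu || py[i] > 0) ? pg[i] : 0.0;
        pm[i] = v;
        sb += v;
        sg += v * px[i];
      }
      dbeta[c] += sb;
      dgamma[c] += sg;
    }
  return List::create(_["g"] = g, _["dbeta"] = dbeta, _["dgamma"] = dgamma);
}

// gx = sc[c] * (g - am[c] - xhat * bm[c])
// [[Rcpp::export(name = ".cm_bn_bwd2")]]
NumericVector cm_bn_bwd2(NumericVector g, NumericVector xhat,
                         NumericVector sc, NumericVector am,
                         NumericVector bm) {
  IntegerVector d = tdim(g);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector gx = make4(d[0], d[1], C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)b * C + c) * HW;
      const double* pg = g.begin() + off;
      const double* px = xhat.begin() + off;
      double* q = gx.begin() + off;
      const double s = sc[c], a = am[c], bb = bm[c];
      for (int i = 0; i < HW; ++i) q[i] = s * (pg[i] - a - px[i] * bb);
    }
  return gx;
}

// xhat = (x - mu[c]) * inv_sd[c]
// [[Rcpp::export(name = ".cm_normalize")]]
NumericVector cm_normalize(NumericVector x, NumericVector mu,
                           NumericVector inv_sd) {
  IntegerVector d = tdim(x);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector y = make4(d[0], d[1], C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)b * C + c) * HW;
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      const double m = mu[c], s = inv_sd[c];
      for (int i = 0; i < HW; ++i) q[i] = (p[i] - m) * s;
    }
  return y;
}

// per-pixel softmax over channels
// [[Rcpp::export(name = ".cm_softmax_channels")]]
NumericVector cm_softmax_channels(NumericVector z) {
  IntegerVector d = tdim(z);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  NumericVector p = make4(d[0], d[1], C, B);
  std::vector<double> e(C);
  for (int b = 0; b < B; ++b) {
    const double* zb = z.begin() + (size_t)b * C * HW;
    double* pb = p.begin() + (size_t)b * C * HW;
    for (int i = 0; i < HW; ++i) {
      double m = zb[i];
      for (int c = 1; c < C; ++c) {
        double v = zb[i + (size_t)c * HW];
        if (v > m) m = v;
      }
      double s = 0;
      for (int c = 0; c < C; ++c) {
        e[c] = std::exp(zb[i + (size_t)c * HW] - m);
        s += e[c];
      }
      for (int c = 0; c < C; ++c) pb[i + (size_t)c * HW] = e[c] / s;
    }
  }
  return p;
}

// combined cross-entropy-through-softmax gradient wrt logits
// [[Rcpp::export(name = ".cm_softmax_cel_grad")]]
NumericVector cm_softmax_cel_grad(NumericVector y, NumericVector p,
                                  double eps) {
  IntegerVector d = tdim(p);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  const double n = (double)HW * C * B;
  NumericVector gz = make4(d[0], d[1], C, B);
  std::vector<double> g(C);
  for (int b = 0; b < B; ++b) {
    const double* yb = y.begin() + (size_t)b * C * HW;
    const double* pb = p.begin() + (size_t)b * C * HW;
    double* gb = gz.begin() + (size_t)b * C * HW;
    for (int i = 0; i < HW; ++i) {
      double s = 0;
      for (int c = 0; c < C; ++c) {
        const size_t j = i + (size_t)c * HW;
        double pc = pb[j];
        if (pc < eps) pc = eps;
        if (pc > 1 - eps) pc = 1 - eps;
        g[c] = -(yb[j] / pc - (1 - yb[j]) / (1 - pc)) / n;
        s += g[c] * pb[j];
      }
      for (int c = 0; c < C; ++c) {
        const size_t j = i + (size_t)c * HW;
        gb[j] = pb[j] * (g[c] - s);
      }
    }
  }
  return gz;
}

// elementwise binary cross-entropy, mean over all elements
// [[Rcpp::export(name = ".cm_cel")]]
double cm_cel(NumericVector y, NumericVector p, double eps) {
  const R_xlen_t n = y.size();
  double s = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    // each log argument is clipped from below so an exact prediction of a
    // binary target contributes exactly zero
    const double p1 = p[i] < eps ? eps : p[i];
    const double p0 = 1 - p[i] < eps ? eps : 1 - p[i];
    s += y[i] * std::log(p1) + (1 - y[i]) * std::log(p0);
  }
  return -s / n;
}

// channel concatenation / split (per-sample contiguous memcpy)
// [[Rcpp::export(name = ".cm_concat_channels")]]
NumericVector cm_concat_channels(List xs) {
  const int nx = xs.size();
  std::vector<NumericVector> v;
  int Ct = 0;
  IntegerVector d0 = tdim(xs[0]);
  for (int k = 0; k < nx; ++k) {
    NumericVector xk = xs[k];
    v.push_back(xk);
    Ct += tdim(xk)[2];
  }
  const int HW = d0[0] * d0[1], B = d0[3];
  NumericVector y = make4(d0[0], d0[1], Ct, B);
  for (int b = 0; b < B; ++b) {
    double* q = y.begin() + (size_t)b * Ct * HW;
    for (int k = 0; k < nx; ++k) {
      const int Ck = tdim(v[k])[2];
      const double* p = v[k].begin() + (size_t)b * Ck * HW;
      std::copy(p, p + (size_t)Ck * HW, q);
      q += (size_t)Ck * HW;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cm_split_channels")]]
List cm_split_channels(NumericVector g, IntegerVector sizes) {
  IntegerVector d = tdim(g);
  const int HW = d[0] * d[1], C = d[2], B = d[3];
  const int np = sizes.size();
  List out(np);
  int at = 0;
  for (int k = 0; k < np; ++k) {
    const int Ck = sizes[k];
    NumericVector y = make4(d[0], d[1], Ck, B);
    for (int b = 0; b < B; ++b) {
      const double* p = g.begin() + ((size_t)b * C + at) * HW;
      double* q = y.begin() + (size_t)b * Ck * HW;
      std::copy(p, p + (size_t)Ck * HW, q);
    }
    out[k] = y;
    at += Ck;
  }
  return out;
}
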