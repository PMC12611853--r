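// Convolution / pooling / resampling kernels for the autodiff core.
// All rank-4 arrays use the (H, W, C, N) column-major layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a rank-4 array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// im2col: A is (Ho*Wo) x (kh*kw*C); column order matches the flattened
// (kh, kw, C, Co) weight layout so that y = A * matrix(w, kh*kw*C, Co).
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, arma::mat &A) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int col = dh + kh * (dw + kw * c);
        double *a = A.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + dw;
          double *arow = a + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) arow[ho] = 0.0;
            continue;
          }
          const double *xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - ph + dh;
            arow[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &A, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, double *gx) {
  for (int c = 0; c < C; ++c) {
    double *xc = gx + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int col = dh + kh * (dw + kw * c);
        const double *a = A.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + dw;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (size_t)H * wi;
          const double *arow = a + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - ph + dh;
            if (hi >= 0 && hi < H) xcol[hi] += arow[ho];
          }
        }
      }
    }
  }
}

// Gather the (H,W,C,N) array into an (H*W*N) x C matrix (samples stacked
// row-wise) so stride-1 convolutions become one GEMM per kernel offset.
// Stride-1 GEMMs run in single precision, the standard arithmetic for CNN
// training; results are returned as doubles.
template <typename MT>
static void stack_rows(const double *x, int H, int W, int C, int N, MT &X) {
  typedef typename MT::elem_type T;
  size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *src = x + HW * (c + (size_t)C * n);
      T *dst = X.colptr(c) + HW * n;
      for (size_t i = 0; i < HW; ++i) dst[i] = (T)src[i];
    }
}

template <typename MT>
static void unstack_rows(const MT &X, int H, int W, int C, int N, double *x) {
  typedef typename MT::elem_type T;
  size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const T *src = X.colptr(c) + HW * n;
      double *dst = x + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) dst[i] = (double)src[i];
    }
}

// Y(ho, wo) += Z(ho + dh - ph, wo + dw - pw) over the valid rectangle,
// for every column (channel) and sample of the stacked matrices.
template <typename MT>
static void shift_accum(const MT &Z, MT &Y, int H, int W, int N,
                        int dh, int dw) {
  typedef typename MT::elem_type T;
  int ho0 = std::max(0, -dh), ho1 = std::min(H - 1, H - 1 - dh);
  int wo0 = std::max(0, -dw), wo1 = std::min(W - 1, W - 1 - dw);
  if (ho1 < ho0 || wo1 < wo0) return;
  int len = ho1 - ho0 + 1;
  size_t HW = (size_t)H * W;
  for (size_t c = 0; c < Z.n_cols; ++c) {
    const T *zc = Z.colptr(c);
    T *yc = Y.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int wo = wo0; wo <= wo1; ++wo) {
        const T *zp = zc + HW * n + (size_t)H * (wo + dw) + (ho0 + dh);
        T *yp = yc + HW * n + (size_t)H * wo + ho0;
        for (int i = 0; i < len; ++i) yp[i] += zp[i];
      }
  }
}

// Shifted copy with zero fill: Dst(h, w) = Src(h + dh, w + dw) (0 outside).
template <typename MT>
static void shift_copy(const MT &S, MT &D, int H, int W, int N,
                       int dh, int dw) {
  D.zeros();
  shift_accum(S, D, H, W, N, dh, dw);
}

template <typename MT>
static void offset_weights(const double *w, int kh, int kw, int C, int Co,
                           int dh, int dw, MT &Woff) {
  typedef typename MT::elem_type T;
  for (int co = 0; co < Co; ++co)
    for (int c = 0; c < C; ++c)
      Woff(c, co) = (T)w[dh + kh * ((size_t)dw + kw * (c + (size_t)C * co))];
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int ph, int pw) {
  int dx[4], dw_[4];
  dims4(x, dx); dims4(w, dw_);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw_[0], kw = dw_[1], Co = dw_[3];
  if (dw_[2] != C) stop("conv: input has %d channels but kernel expects %d", C, dw_[2]);
  int Ho = (H + 2 * ph - kh) / stride + 1;
  int Wo = (W + 2 * pw - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv: kernel larger than padded input");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Co * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  if (stride == 1 && Ho == H && Wo == W) {
    arma::fmat X((size_t)H * W * N, C), Y((size_t)H * W * N, Co, arma::fill::zeros);
    arma::fmat Woff(C, Co), Z((size_t)H * W * N, Co);
    stack_rows(x.begin(), H, W, C, N, X);
    for (int dw2 = 0; dw2 < kw; ++dw2)
      for (int dh = 0; dh < kh; ++dh) {
        offset_weights(w.begin(), kh, kw, C, Co, dh, dw2, Woff);
        Z = X * Woff;
        shift_accum(Z, Y, H, W, N, dh - ph, dw2 - pw);
      }
    unstack_rows(Y, H, W, Co, N, y.begin());
    return y;
  }
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, Co, false, true);
  arma::mat A((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, A);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    Y = A * Wm;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector gy, NumericVector w,
                                int stride, int ph, int pw, int H, int W) {
  int dg[4], dw_[4];
  dims4(gy, dg); dims4(w, dw_);
  int Ho = dg[0], Wo = dg[1], Co = dg[2], N = dg[3];
  int kh = dw_[0], kw = dw_[1], C = dw_[2];
  if (dw_[3] != Co) stop("conv bwd: channel mismatch");
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  if (stride == 1 && Ho == H && Wo == W) {
    arma::fmat G((size_t)H * W * N, Co), GX((size_t)H * W * N, C, arma::fill::zeros);
    arma::fmat Woff(C, Co), Z((size_t)H * W * N, C);
    stack_rows(gy.begin(), H, W, Co, N, G);
    for (int dw2 = 0; dw2 < kw; ++dw2)
      for (int dh = 0; dh < kh; ++dh) {
        offset_weights(w.begin(), kh, kw, C, Co, dh, dw2, Woff);
        Z = G * Woff.t();
        shift_accum(Z, GX, H, W, N, ph - dh, pw - dw2);
      }
    unstack_rows(GX, H, W, C, N, gx.begin());
    return gx;
  }
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, Co, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double *>(gy.begin()) + (size_t)Ho * Wo * Co * n,
                (size_t)Ho * Wo, Co, false, true);
    arma::mat A = G * Wm.t();
    col2im(A, H, W, C, kh, kw, stride, ph, pw, Ho, Wo,
           gx.begin() + (size_t)H * W * C * n);
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_w(NumericVector x, NumericVector gy,
                             int stride, int ph, int pw, int kh, int kw) {
  int dx[4], dg[4];
  dims4(x, dx); dims4(gy, dg);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = dg[0], Wo = dg[1], Co = dg[2];
  if (dg[3] != N) stop("conv bwd w: batch mismatch");
  int ph_ = ph, pw_ = pw;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C * Co));
  out.attr("dim") = IntegerVector::create(kh, kw, C, Co);
  if (stride == 1 && Ho == H && Wo == W) {
    arma::fmat X((size_t)H * W * N, C), G((size_t)H * W * N, Co);
    arma::fmat Gt((size_t)H * W * N, Co), Gw(C, Co);
    stack_rows(x.begin(), H, W, C, N, X);
    stack_rows(gy.begin(), H, W, Co, N, G);
    for (int dw2 = 0; dw2 < kw; ++dw2)
      for (int dh = 0; dh < kh; ++dh) {
        shift_copy(G, Gt, H, W, N, ph_ - dh, pw_ - dw2);
        Gw = X.t() * Gt;
        for (int co = 0; co < Co; ++co)
          for (int c = 0; c < C; ++c)
            out[dh + kh * ((size_t)dw2 + kw * (c + (size_t)C * co))] = (double)Gw(c, co);
      }
    return out;
  }
  arma::mat Gw((size_t)kh * kw * C, Co, arma::fill::zeros);
  arma::mat A((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, A);
    arma::mat G(const_cast<double *>(gy.begin()) + (size_t)Ho * Wo * Co * n,
                (size_t)Ho * Wo, Co, false, true);
    Gw += A.t() * G;
  }
  std::copy(Gw.begin(), Gw.end(), out.begin());
  return out;
}

// 2x2 max pooling with stride 2; returns values and 1-based argmax indices.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  int d[4];
  dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even, got %dx%d", H, W);
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t len = (R_xlen_t)Ho * Wo * C * N;
  NumericVector y(Rf_allocVector(REALSXP, len));
  IntegerVector idx(Rf_allocVector(INTSXP, len));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = (size_t)(2 * ho) + H * (size_t)(2 * wo);
          size_t best = i00;
          double v = xc[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > v) { v = xc[cand[t]]; best = cand[t]; }
          R_xlen_t oo = (R_xlen_t)ho + Ho * ((R_xlen_t)wo + Wo * ((R_xlen_t)c + (R_xlen_t)C * n));
          y[oo] = v;
          idx[oo] = (int)(base + best) + 1;
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest(NumericVector x, int f) {
  int d[4];
  dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H * f, Wo = W * f;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double *xcol = xc + (size_t)H * (wo / f);
        double *ycol = yc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) ycol[ho] = xcol[ho / f];
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_bwd(NumericVector g, int f) {
  int d[4];
  dims4(g, d);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho / f, W = Wo / f;
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gc = g.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double *xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double *xcol = xc + (size_t)H * (wo / f);
        const double *gcol = gc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) xcol[ho / f] += gcol[ho];
      }
    }
  return gx;
}

// ---- batch-norm / activation helpers (hot path) --------------------------

// [[Rcpp::export]]
List cpp_chan_mean_var(NumericVector x) {
  int d[4];
  dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  NumericVector mu(C), va(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += p[i];
      mu[c] += s;
    }
  double m = (double)HW * N;
  for (int c = 0; c < C; ++c) mu[c] /= m;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (size_t)C * n);
      double s = 0, mc = mu[c];
      for (size_t i = 0; i < HW; ++i) { double dlt = p[i] - mc; s += dlt * dlt; }
      va[c] += s;
    }
  for (int c = 0; c < C; ++c) va[c] /= m;
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = x * a[channel] + b[channel]
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  int d[4];
  dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (size_t)C * n);
      double *q = y.begin() + HW * (c + (size_t)C * n);
      double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * ac + bc;
    }
  return y;
}

// Training-mode batch-norm backward from the normalized activations.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector xhat, NumericVector gamma,
                NumericVector inv) {
  int d[4];
  dims4(g, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector s1(C), s2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = g.begin() + HW * (c + (size_t)C * n);
      const double *xp = xhat.begin() + HW * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t i = 0; i < HW; ++i) { a += gp[i]; b += gp[i] * xp[i]; }
      s1[c] += a; s2[c] += b;
    }
  NumericVector gx(Rf_allocVector(REALSXP, g.size()));
  gx.attr("dim") = g.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = g.begin() + HW * (c + (size_t)C * n);
      const double *xp = xhat.begin() + HW * (c + (size_t)C * n);
      double *op = gx.begin() + HW * (c + (size_t)C * n);
      double sc = gamma[c] * inv[c], m1 = s1[c] / m, m2 = s2[c] / m;
      for (size_t i = 0; i < HW; ++i) op[i] = sc * (gp[i] - m1 - xp[i] * m2);
    }
  // gradient w.r.t. gamma is s2, w.r.t. beta is s1
  return List::create(_["gx"] = gx, _["ggamma"] = s2, _["gbeta"] = s1);
}

// Fused in-place Adam step with L2 weight decay. `tensors` are parameter
// environments holding `v` (value) and `grad`; moment buffers are owned by
// the optimizer and updated in place. Parameter values are duplicated
// before the in-place update when R still shares them.
// [[Rcpp::export]]
void cpp_adam_step(List tensors, List ms, List vs, int t, double lr,
                   double wd, double b1, double b2, double eps) {
  double bc1 = 1.0 - std::pow(b1, (double)t);
  double bc2 = 1.0 - std::pow(b2, (double)t);
  for (int k = 0; k < tensors.size(); ++k) {
    Environment e = tensors[k];
    RObject gro = e.get("grad");
    if (gro.isNULL()) continue;
    NumericVector g(gro);
    SEXP vv = e.get("v");
    if (MAYBE_SHARED(vv)) {
      vv = Rf_duplicate(vv);
      e.assign("v", vv);
    }
    double *p = REAL(vv);
    NumericVector m = ms[k], v = vs[k];
    R_xlen_t n = g.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      double gi = g[i] + wd * p[i];
      double mi = b1 * m[i] + (1.0 - b1) * gi;
      double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
      m[i] = mi; v[i] = vi;
      p[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
    }
  }
}

// Exact GELU: value and derivative from a single erf/exp evaluation.
// [[Rcpp::export]]
List cpp_gelu_both(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  NumericVector d(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  d.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475244;
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double cdf = 0.5 * (1.0 + std::erf(xi * inv_sqrt2));
    y[i] = xi * cdf;
    d[i] = cdf + xi * inv_sqrt2pi * std::exp(-0.5 * xi * xi);
  }
  return List::create(_["y"] = y, _["d"] = d);
}

// Exact GELU and its derivative
// [[Rcpp::export]]
NumericVector cpp_gelu(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475244;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    y[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * inv_sqrt2));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_grad(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475244;
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    y[i] = 0.5 * (1.0 + std::erf(xi * inv_sqrt2)) +
           xi * inv_sqrt2pi * std::exp(-0.5 * xi * xi);
  }
  return y;
}

// Bilinear interpolation weights for integer upsampling, half-pixel centers.
static void bilin_map(int Ho, int H, int f, std::vector<int> &i0,
                      std::vector<int> &i1, std::vector<double> &w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) / f - 0.5;
    int lo = (int)std::floor(src);
    double w = src - lo;
    if (lo < 0) { lo = 0; w = 0.0; }
    int hi = lo + 1;
    if (hi > H - 1) { hi = H - 1; w = 0.0; }
    i0[o] = lo; i1[o] = hi; w1[o] = w;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bilinear(NumericVector x, int f) {
  int d[4];
  dims4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H * f, Wo = W * f;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_map(Ho, H, f, h0, h1, hw);
  bilin_map(Wo, W, f, w0, w1v, ww);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double *cl = xc + (size_t)H * w0[wo];
        const double *cr = xc + (size_t)H * w1v[wo];
        double bw = ww[wo];
        double *ycol = yc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          double top = cl[h0[ho]] * (1 - bw) + cr[h0[ho]] * bw;
          double bot = cl[h1[ho]] * (1 - bw) + cr[h1[ho]] * bw;
          ycol[ho] = top * (1 - hw[ho]) + bot * hw[ho];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bilinear_bwd(NumericVector g, int f) {
  int d[4];
  dims4(g, d);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho / f, W = Wo / f;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_map(Ho, H, f, h0, h1, hw);
  bilin_map(Wo, W, f, w0, w1v, ww);
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gc = g.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double *xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double *cl = xc + (size_t)H * w0[wo];
        double *cr = xc + (size_t)H * w1v[wo];
        double bw = ww[wo];
        const double *gcol = gc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          double gv = gcol[ho];
          cl[h0[ho]] += gv * (1 - bw) * (1 - hw[ho]);
          cr[h0[ho]] += gv * bw * (1 - hw[ho]);
          cl[h1[ho]] += gv * (1 - bw) * hw[ho];
          cr[h1[ho]] += gv * bw * hw[ho];
        }
      }
    }
  return gx;
}
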