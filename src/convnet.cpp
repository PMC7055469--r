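// Minimal CNN layer kernels: single-precision im2col convolution, 2x2 pooling,
// and connected-component labelling for the silique assembly stage.
//
// Tensor layout everywhere: column-major R array with dim c(H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)), all 0-based here.
// Convolution weights are a (kh*kw*C) x F matrix whose row index is
// dh + kh*(dw + kw*c), matching the im2col row layout below.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col, transposed layout: Kt is P x (kh*kw*C) with P = Ho*Wo*N and
// row index p = ho + Ho*(wo + Wo*n). For a fixed kernel tap (dh, dw, c) the
// run over ho is contiguous in both Kt and x, so the fill is memcpy-like.
static void im2col_t(const double *x, int H, int W, int C, int N,
                     int kh, int kw, int pad, arma::fmat &Kt) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        float *col = Kt.colptr(r);
        for (int n = 0; n < N; ++n) {
          const double *xcn = x + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            float *dst = col + (size_t)Ho * (wo + (size_t)Wo * n);
            const int w = wo - pad + dw;
            if (w < 0 || w >= W) {
              std::memset(dst, 0, sizeof(float) * Ho);
              continue;
            }
            const double *xc = xcn + (size_t)H * w;
            // h = ho - pad + dh for ho in [0, Ho)
            const int h0 = dh - pad;
            int lead = (h0 < 0) ? -h0 : 0;          // ho with h < 0
            int valid = Ho - lead;
            if (h0 + Ho > H) valid -= (h0 + Ho - H); // ho with h >= H
            if (valid < 0) valid = 0;
            for (int i = 0; i < lead; ++i) dst[i] = 0.0f;
            const double *srcp = xc + h0 + lead;
            for (int i = 0; i < valid; ++i) dst[lead + i] = (float)srcp[i];
            for (int i = lead + valid; i < Ho; ++i) dst[i] = 0.0f;
          }
        }
      }
}

static arma::fmat as_fmat(const NumericMatrix &w) {
  arma::fmat Wf(w.nrow(), w.ncol());
  const double *p = &w[0];
  float *q = Wf.memptr();
  const size_t nn = (size_t)w.nrow() * w.ncol();
  for (size_t i = 0; i < nn; ++i) q[i] = (float)p[i];
  return Wf;
}

// [[Rcpp::export]]
List cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                        NumericMatrix w, NumericVector bias,
                        int kh, int kw, int pad, bool keep_im2col) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const int F = w.ncol();
  if (w.nrow() != kh * kw * C) stop("weight rows do not match kernel size and input channels");
  const arma::uword P = (arma::uword)Ho * Wo * N;
  XPtr<arma::fmat> kt(new arma::fmat(P, (arma::uword)kh * kw * C), true);
  arma::fmat &Kt = *kt;
  im2col_t(REAL(x), H, W, C, N, kh, kw, pad, Kt);
  arma::fmat Yt = Kt * as_fmat(w);  // P x F
  NumericVector out((R_xlen_t)Ho * Wo * F * N);
  double *o = REAL(out);
  for (int f = 0; f < F; ++f) {
    const float *col = Yt.colptr(f);
    const double bf = bias[f];
    for (int n = 0; n < N; ++n) {
      double *dst = o + (size_t)Ho * Wo * (f + (size_t)F * n);
      const float *sp = col + (size_t)Ho * Wo * n;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = (double)sp[i] + bf;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  if (keep_im2col)
    return List::create(_["y"] = out, _["kt"] = kt);
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, NumericVector dy,
                         int kh, int kw, int pad, SEXP kt_cache) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const int F = w.ncol();
  const arma::uword P = (arma::uword)Ho * Wo * N;
  arma::fmat Kt_local;
  arma::fmat *Ktp;
  if (kt_cache != R_NilValue) {
    XPtr<arma::fmat> kt(kt_cache);
    Ktp = kt.get();
  } else {
    Kt_local.set_size(P, (arma::uword)kh * kw * C);
    im2col_t(REAL(x), H, W, C, N, kh, kw, pad, Kt_local);
    Ktp = &Kt_local;
  }
  arma::fmat &Kt = *Ktp;
  // gather dy (Ho,Wo,F,N) into dYt (P x F)
  arma::fmat dYt(P, F);
  const double *dyp = REAL(dy);
  for (int f = 0; f < F; ++f) {
    float *col = dYt.colptr(f);
    for (int n = 0; n < N; ++n) {
      const double *sp = dyp + (size_t)Ho * Wo * (f + (size_t)F * n);
      float *dst = col + (size_t)Ho * Wo * n;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = (float)sp[i];
    }
  }
  arma::fmat Wf = as_fmat(w);
  arma::fmat dW = Kt.t() * dYt;       // (kh*kw*C) x F
  arma::frowvec db = arma::sum(dYt, 0);
  arma::fmat dKt = dYt * Wf.t();      // P x (kh*kw*C)

  // col2im: reverse of im2col_t, accumulating into dx
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *dxp = REAL(dx);
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const float *col = dKt.colptr(r);
        for (int n = 0; n < N; ++n) {
          double *xcn = dxp + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const float *sp = col + (size_t)Ho * (wo + (size_t)Wo * n);
            const int w2 = wo - pad + dw;
            if (w2 < 0 || w2 >= W) continue;
            double *xc = xcn + (size_t)H * w2;
            const int h0 = dh - pad;
            int lead = (h0 < 0) ? -h0 : 0;
            int valid = Ho - lead;
            if (h0 + Ho > H) valid -= (h0 + Ho - H);
            if (valid < 0) valid = 0;
            double *dst = xc + h0 + lead;
            for (int i = 0; i < valid; ++i) dst[i] += (double)sp[lead + i];
          }
        }
      }
  dx.attr("dim") = xdim;
  NumericMatrix dWr(w.nrow(), F);
  for (int j = 0; j < F; ++j)
    for (int i = 0; i < w.nrow(); ++i) dWr(i, j) = (double)dW(i, j);
  NumericVector dbr(F);
  for (int f = 0; f < F; ++f) dbr[f] = (double)db(f);
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// 2x2 max pooling, stride 2. Returns pooled values and the linear (1-based)
// index of each argmax into the input array, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (size_t)2 * ho + (size_t)H * (2 * wo);
          double bv = xp[best];
          const size_t cand[3] = {base + (size_t)2 * ho + 1 + (size_t)H * (2 * wo),
                                  base + (size_t)2 * ho + (size_t)H * (2 * wo + 1),
                                  base + (size_t)2 * ho + 1 + (size_t)H * (2 * wo + 1)};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          // output laid out (Ho,Wo,C,N): position ho + Ho*(wo + Wo*(c + C*n))
          o = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          yp[o] = bv;
          ip[o] = (int)(best + 1);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *dxp = REAL(dx);
  const double *dyp = REAL(dy);
  const int *ip = INTEGER(idx);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i] - 1] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double *p0 = xp + base + (size_t)2 * ho + (size_t)H * (2 * wo);
          const double *p1 = p0 + H;
          yp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))] =
              0.25 * (p0[0] + p0[1] + p1[0] + p1[1]);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *dxp = REAL(dx);
  const double *dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g =
              0.25 * dyp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))];
          double *p0 = dxp + base + (size_t)2 * ho + (size_t)H * (2 * wo);
          double *p1 = p0 + H;
          p0[0] += g; p0[1] += g; p1[0] += g; p1[1] += g;
        }
    }
  dx.attr("dim") = xdim;
  return dx;
}

// Connected components of equal-valued cells in an integer matrix.
// Cells whose value equals `bg` get component id 0. `conn` is 4 or 8.
// Components are labelled 1, 2, ... in scan order; two cells join iff they are
// neighbours under `conn` AND carry the same value.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix m, int bg, int conn) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (conn == 8) ? 8 : 4;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (m(r, c) == bg || lab(r, c) != 0) continue;
      const int v = m(r, c);
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        const auto rc = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int r2 = rc.first + dr8[k], c2 = rc.second + dc8[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (lab(r2, c2) == 0 && m(r2, c2) == v) {
            lab(r2, c2) = next;
            stack.push_back({r2, c2});
          }
        }
      }
    }
  return lab;
}

// Batch normalisation over (H, W, N) per channel, everything in one place:
// batch moments (training) or running moments (inference), normalised
// activations and the affine output. Returns what the backward pass needs.
// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, IntegerVector xdim,
                    NumericVector gamma, NumericVector beta,
                    NumericVector run_mean, NumericVector run_var,
                    bool training, double momentum, double eps,
                    bool relu, bool want_xhat) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  const double *xp = REAL(x);
  NumericVector mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double *p = xp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = run_mean[c]; var[c] = run_var[c]; }
  }
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector y(x.size());
  NumericVector xhat(want_xhat ? x.size() : 0);
  double *yp = REAL(y);
  double *xh = want_xhat ? REAL(xhat) : nullptr;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double mc = mu[c], ic = istd[c], g = gamma[c], b = beta[c];
      const size_t off = HW * (c + (size_t)C * n);
      const double *p = xp + off;
      double *r = yp + off;
      if (want_xhat) {
        double *q = xh + off;
        if (relu) {
          for (size_t i = 0; i < HW; ++i) {
            const double z = (p[i] - mc) * ic;
            q[i] = z;
            const double v = z * g + b;
            r[i] = v > 0 ? v : 0.0;
          }
        } else {
          for (size_t i = 0; i < HW; ++i) {
            const double z = (p[i] - mc) * ic;
            q[i] = z;
            r[i] = z * g + b;
          }
        }
      } else {
        if (relu) {
          for (size_t i = 0; i < HW; ++i) {
            const double v = (p[i] - mc) * ic * g + b;
            r[i] = v > 0 ? v : 0.0;
          }
        } else {
          for (size_t i = 0; i < HW; ++i) r[i] = (p[i] - mc) * ic * g + b;
        }
      }
    }
  NumericVector nrm(C), nrv(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      nrm[c] = momentum * run_mean[c] + (1 - momentum) * mu[c];
      nrv[c] = momentum * run_var[c] + (1 - momentum) * var[c];
    }
  } else {
    nrm = run_mean; nrv = run_var;
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["run_mean"] = nrm, _["run_var"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector xhat, IntegerVector xdim, NumericVector dy,
                     NumericVector gamma, NumericVector istd, bool training,
                     Nullable<NumericVector> relu_y = R_NilValue) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  const double *xh = REAL(xhat);
  const double *dyp = REAL(dy);
  const double *yp = nullptr;
  if (relu_y.isNotNull()) {
    NumericVector yv(relu_y);
    yp = REAL(yv);
  }
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double *q = xh + off, *d = dyp + off;
      double sg = 0, sb = 0;
      if (yp) {
        const double *y = yp + off;
        for (size_t i = 0; i < HW; ++i)
          if (y[i] > 0) { sg += d[i] * q[i]; sb += d[i]; }
      } else {
        for (size_t i = 0; i < HW; ++i) { sg += d[i] * q[i]; sb += d[i]; }
      }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  NumericVector dx(xhat.size());
  double *dxp = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double *q = xh + off, *d = dyp + off;
      double *o = dxp + off;
      const double gi = gamma[c] * istd[c];
      const double *y = yp ? yp + off : nullptr;
      if (training) {
        const double tb = dbeta[c] / m, tg = dgamma[c] / m;
        if (y) {
          for (size_t i = 0; i < HW; ++i) {
            const double dd = y[i] > 0 ? d[i] : 0.0;
            o[i] = gi * (dd - tb - q[i] * tg);
          }
        } else {
          for (size_t i = 0; i < HW; ++i) o[i] = gi * (d[i] - tb - q[i] * tg);
        }
      } else {
        if (y) { for (size_t i = 0; i < HW; ++i) o[i] = y[i] > 0 ? gi * d[i] : 0.0; }
        else { for (size_t i = 0; i < HW; ++i) o[i] = gi * d[i]; }
      }
    }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}


// Inverted dropout using the R RNG stream (deterministic under set.seed).
// [[Rcpp::export]]
List cpp_dropout_forward(NumericVector x, double rate) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  NumericVector mask(n);
  const double *xp = REAL(x);
  double *yp = REAL(y), *mp = REAL(mask);
  const double scale = 1.0 / (1.0 - rate);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m = (unif_rand() >= rate) ? scale : 0.0;
    mp[i] = m;
    yp[i] = xp[i] * m;
  }
  PutRNGstate();
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}


// Concatenate along the channel dimension: (H,W,Ca,N) + (H,W,Cb,N).
// [[Rcpp::export]]
NumericVector cpp_concat_channels(NumericVector a, IntegerVector adim,
                                  NumericVector b, IntegerVector bdim) {
  const int H = adim[0], W = adim[1], Ca = adim[2], N = adim[3], Cb = bdim[2];
  const size_t HW = (size_t)H * W;
  NumericVector out((R_xlen_t)HW * (Ca + Cb) * N);
  double *o = REAL(out);
  const double *pa = REAL(a), *pb = REAL(b);
  for (int n = 0; n < N; ++n) {
    std::memcpy(o + HW * (size_t)(Ca + Cb) * n, pa + HW * (size_t)Ca * n,
                sizeof(double) * HW * Ca);
    std::memcpy(o + HW * ((size_t)(Ca + Cb) * n + Ca), pb + HW * (size_t)Cb * n,
                sizeof(double) * HW * Cb);
  }
  out.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  return out;
}

// Split (H,W,C,N) into the first c_keep channels and the rest.
// [[Rcpp::export]]
List cpp_split_channels(NumericVector x, IntegerVector xdim, int c_keep) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const int Cr = C - c_keep;
  NumericVector head((R_xlen_t)HW * c_keep * N), tail((R_xlen_t)HW * Cr * N);
  const double *p = REAL(x);
  double *h = REAL(head), *t = REAL(tail);
  for (int n = 0; n < N; ++n) {
    std::memcpy(h + HW * (size_t)c_keep * n, p + HW * (size_t)C * n,
                sizeof(double) * HW * c_keep);
    std::memcpy(t + HW * (size_t)Cr * n, p + HW * ((size_t)C * n + c_keep),
                sizeof(double) * HW * Cr);
  }
  head.attr("dim") = IntegerVector::create(H, W, c_keep, N);
  tail.attr("dim") = IntegerVector::create(H, W, Cr, N);
  return List::create(_["head"] = head, _["tail"] = tail);
}
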