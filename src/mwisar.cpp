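// Numerical kernels: CSAR field synthesis, valid/padded 2-D convolution via
// im2col + GEMM, and max pooling. Sample-at-a-time im2col keeps peak memory
// bounded by one column matrix regardless of batch size. All loops have a
// fixed accumulation order so results are bit-reproducible on one machine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Backscattered field for point scatterers under the monostatic CSAR model.
// Es(f, phi) = sum_p w_p * exp(-i * coef * f * R_p(phi)), coef = 4*pi*sqrt(eps_r*mu_r)/c.
// px, py in cm; freqs in Hz; angles in radians; R0 in cm; c in m/s.
// [[Rcpp::export]]
ComplexMatrix cs_field_cpp(NumericVector px, NumericVector py, NumericVector w,
                           NumericVector freqs_hz, NumericVector angles_rad,
                           double R0_cm, double eps_r, double mu_r, double c0,
                           double amplitude) {
  const int P = px.size(), nf = freqs_hz.size(), na = angles_rad.size();
  const double coef = 4.0 * M_PI * std::sqrt(eps_r * mu_r) / c0;
  ComplexMatrix out(nf, na);
  std::vector<double> theta(P); // coef * R_p, distance in metres
  for (int a = 0; a < na; ++a) {
    const double ax = R0_cm * std::cos(angles_rad[a]);
    const double ay = R0_cm * std::sin(angles_rad[a]);
    for (int p = 0; p < P; ++p) {
      const double dx = px[p] - ax, dy = py[p] - ay;
      theta[p] = coef * 0.01 * std::sqrt(dx * dx + dy * dy);
    }
    for (int f = 0; f < nf; ++f) {
      double re = 0.0, im = 0.0;
      const double ff = freqs_hz[f];
      for (int p = 0; p < P; ++p) {
        const double ph = -ff * theta[p];
        re += w[p] * std::cos(ph);
        im += w[p] * std::sin(ph);
      }
      out(f, a) = Rcomplex{amplitude * re, amplitude * im};
    }
  }
  return out;
}

static inline void im2col_one(const double* x, int H, int W, int C,
                              int kh, int kw, int ph, int pw,
                              int oH, int oW, arma::mat& col) {
  // col is (kh*kw*C) x (oH*oW); row index r = i_kh + kh*(i_kw + kw*c)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* cr = col.memptr() + r; // stride col.n_rows per column
        for (int ow = 0; ow < oW; ++ow) {
          const int xw = ow + j - pw;
          for (int oh = 0; oh < oH; ++oh) {
            const int xh = oh + i - ph;
            double v = 0.0;
            if (xh >= 0 && xh < H && xw >= 0 && xw < W)
              v = xc[(size_t)xw * H + xh];
            cr[(size_t)(ow * oH + oh) * col.n_rows] = v;
          }
        }
      }
    }
  }
}

// activation codes: 0 linear, 1 relu, 2 sigmoid (applied elementwise)
static inline void act_inplace(double* p, size_t n, int act) {
  if (act == 1) { for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0; }
  else if (act == 2) { for (size_t i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-p[i])); }
}

// x: (H, W, C, N) array, w: (kh, kw, C, F) array; returns (oH, oW, F, N).
// Optional per-filter bias and fused activation.
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector wt,
                             int ph, int pw, Nullable<NumericVector> bias = R_NilValue,
                             int act = 0) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  if (oH < 1 || oW < 1) stop("kernel larger than (padded) input");
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(wt.begin()), K, F, false, true);
  NumericVector y((R_xlen_t)oH * oW * F * N);
  y.attr("dim") = IntegerVector::create(oH, oW, F, N);
  arma::mat col(K, (size_t)oH * oW);
  const bool has_b = bias.isNotNull();
  NumericVector bv;
  if (has_b) bv = bias.get();
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, col);
    arma::mat yn(y.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW, F, false, true);
    yn = col.t() * Wm;
    if (has_b) for (int f = 0; f < F; ++f) yn.col(f) += bv[f];
    act_inplace(y.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW * F, act);
  }
  return y;
}

// Gradients of the valid/padded convolution. dy: (oH, oW, F, N) is the
// gradient at the (post-activation) output; `out` is the forward output so
// the activation derivative can be applied in place here (dy is modified!).
// Also returns the per-filter bias gradient when wanted.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector wt, NumericVector dy,
                    int ph, int pw, Nullable<NumericVector> out = R_NilValue,
                    int act = 0, bool want_db = false) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int oH = yd[0], oW = yd[1];
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(wt.begin()), K, F, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * C * F);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
  arma::mat dWm(dw.begin(), K, F, false, true);
  NumericVector db(F);
  if (act != 0) {
    NumericVector ov = out.get();
    const R_xlen_t len = dy.size();
    if (act == 1) { for (R_xlen_t i = 0; i < len; ++i) if (ov[i] <= 0) dy[i] = 0; }
    else if (act == 2) { for (R_xlen_t i = 0; i < len; ++i) dy[i] *= ov[i] * (1 - ov[i]); }
  }
  if (want_db) {
    for (int n = 0; n < N; ++n)
      for (int f = 0; f < F; ++f) {
        const double* p = dy.begin() + ((size_t)n * F + f) * oH * oW;
        double s = 0;
        for (int i = 0; i < oH * oW; ++i) s += p[i];
        db[f] += s;
      }
  }
  arma::mat col(K, (size_t)oH * oW), dcol(K, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, col);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * oH * oW * F,
                  (size_t)oH * oW, F, false, true);
    dWm += col * dyn;
    dcol = Wm * dyn.t();
    // col2im: accumulate into dx
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)c * H * W;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int r = i + kh * (j + kw * c);
          const double* dr = dcol.memptr() + r;
          for (int ow = 0; ow < oW; ++ow) {
            const int xw = ow + j - pw;
            if (xw < 0 || xw >= W) continue;
            for (int oh = 0; oh < oH; ++oh) {
              const int xh = oh + i - ph;
              if (xh < 0 || xh >= H) continue;
              dxc[(size_t)xw * H + xh] += dr[(size_t)(ow * oH + oh) * dcol.n_rows];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Non-overlapping max pooling (stride = size, floor division of the extent).
// Returns pooled values and 1-based argmax linear indices into x.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int size) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = H / size, oW = W / size;
  if (oH < 1 || oW < 1) stop("pool size larger than input");
  NumericVector y((R_xlen_t)oH * oW * C * N);
  y.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector idx((R_xlen_t)oH * oW * C * N);
  idx.attr("dim") = IntegerVector::create(oH, oW, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int j = 0; j < size; ++j)
            for (int i = 0; i < size; ++i) {
              const size_t li = base + (size_t)(ow * size + j) * H + (oh * size + i);
              if (x[li] > best) { best = x[li]; bi = li; }
            }
          // write in y's own layout (oh fastest, then ow, then c, then n)
          const size_t yo = (((size_t)n * C + c) * oW + ow) * oH + oh;
          y[yo] = best;
          idx[yo] = (int)(bi + 1);
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const R_xlen_t m = dy.size();
  for (R_xlen_t k = 0; k < m; ++k) dx[idx[k] - 1] += dy[k];
  return dx;
}

// Batch normalization over the channel axis. x is viewed as
// (inner, C, outer): a dense (N, F) matrix is (N, F, 1), a feature map
// (H, W, C, N) is (H*W, C, N). Activation is fused; backward recomputes the
// normalized values from x, so no extra buffer is stored.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, int inner, int C, int outer,
                NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar,
                bool training, double eps, double momentum, int act = 0) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  NumericVector mu(C), va(C), invstd(C), nm(C), nv(C);
  const double m = (double)inner * outer;
  if (training) {
    for (int o = 0; o < outer; ++o)
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + ((size_t)o * C + c) * inner;
        double s = 0;
        for (int i = 0; i < inner; ++i) s += xp[i];
        mu[c] += s;
      }
    for (int c = 0; c < C; ++c) mu[c] /= m;
    for (int o = 0; o < outer; ++o)
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + ((size_t)o * C + c) * inner;
        double s = 0;
        for (int i = 0; i < inner; ++i) { const double d = xp[i] - mu[c]; s += d * d; }
        va[c] += s;
      }
    for (int c = 0; c < C; ++c) {
      va[c] /= m;
      nm[c] = momentum * rmean[c] + (1 - momentum) * mu[c];
      nv[c] = momentum * rvar[c] + (1 - momentum) * va[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; va[c] = rvar[c]; nm[c] = rmean[c]; nv[c] = rvar[c]; }
  }
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(va[c] + eps);
  for (int o = 0; o < outer; ++o)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)o * C + c) * inner;
      double* yp = y.begin() + ((size_t)o * C + c) * inner;
      const double a = invstd[c], g = gamma[c], b = beta[c], u = mu[c];
      for (int i = 0; i < inner; ++i)
        yp[i] = g * (xp[i] - u) * a + b;
    }
  act_inplace(y.begin(), (size_t)n, act);
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd,
                      _["mean"] = nm, _["var"] = nv);
}

// dy is the gradient at the post-activation output; `y` the forward output
// (for the activation derivative), `x` the layer input (to recompute the
// normalized values). dy is modified in place by the activation derivative.
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector y, NumericVector x,
                NumericVector mu, NumericVector invstd,
                NumericVector gamma, int inner, int C, int outer, int act = 0) {
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  const double m = (double)inner * outer;
  if (act == 1) { for (R_xlen_t i = 0; i < dy.size(); ++i) if (y[i] <= 0) dy[i] = 0; }
  else if (act == 2) { for (R_xlen_t i = 0; i < dy.size(); ++i) dy[i] *= y[i] * (1 - y[i]); }
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int o = 0; o < outer; ++o)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)o * C + c) * inner;
      const double* dp = dy.begin() + off;
      const double* xp = x.begin() + off;
      const double u = mu[c], is = invstd[c];
      double a = 0, b = 0;
      for (int i = 0; i < inner; ++i) { a += dp[i]; b += dp[i] * (xp[i] - u) * is; }
      s1[c] += a; s2[c] += b;
    }
  for (int c = 0; c < C; ++c) { dbeta[c] = s1[c]; dgamma[c] = s2[c]; }
  for (int o = 0; o < outer; ++o)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)o * C + c) * inner;
      const double* dp = dy.begin() + off;
      const double* xp = x.begin() + off;
      double* op = dx.begin() + off;
      const double g = gamma[c] * invstd[c];
      const double u = mu[c], is = invstd[c];
      const double a1 = s1[c] / m, a2 = s2[c] / m;
      for (int i = 0; i < inner; ++i)
        op[i] = g * (dp[i] - a1 - (xp[i] - u) * is * a2);
    }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// per-channel sums of a (oH, oW, F, N) gradient (bias gradient)
// [[Rcpp::export]]
NumericVector channel_sums_cpp(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int inner = d[0] * d[1], C = d[2], N = d[3];
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = dy.begin() + ((size_t)n * C + c) * inner;
      double s = 0;
      for (int i = 0; i < inner; ++i) s += p[i];
      out[c] += s;
    }
  return out;
}

// add a per-channel constant to a (H, W, C, N) map in place-ish
// [[Rcpp::export]]
NumericVector add_channel_bias_cpp(NumericVector y, NumericVector b) {
  IntegerVector d = y.attr("dim");
  const int inner = d[0] * d[1], C = d[2], N = d[3];
  NumericVector out = clone(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* p = out.begin() + ((size_t)n * C + c) * inner;
      const double bc = b[c];
      for (int i = 0; i < inner; ++i) p[i] += bc;
    }
  out.attr("dim") = y.attr("dim");
  return out;
}

// Complex convolution: (xr + i xi) * (Wr + i Wi) with shared im2col per
// part. Activation (per-part, Cartesian) and bias are fused.
// [[Rcpp::export]]
List cconv2d_fwd_cpp(NumericVector xr, NumericVector xi,
                     NumericVector wr, NumericVector wi,
                     int ph, int pw,
                     Nullable<NumericVector> br = R_NilValue,
                     Nullable<NumericVector> bi = R_NilValue, int act = 0) {
  IntegerVector xd = xr.attr("dim"), wd = wr.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int oH = H + 2 * ph - kh + 1, oW = W + 2 * pw - kw + 1;
  if (oH < 1 || oW < 1) stop("kernel larger than (padded) input");
  const int K = kh * kw * C;
  arma::mat Wr(const_cast<double*>(wr.begin()), K, F, false, true);
  arma::mat Wi(const_cast<double*>(wi.begin()), K, F, false, true);
  NumericVector yr((R_xlen_t)oH * oW * F * N), yi((R_xlen_t)oH * oW * F * N);
  IntegerVector od = IntegerVector::create(oH, oW, F, N);
  yr.attr("dim") = od; yi.attr("dim") = od;
  arma::mat colr(K, (size_t)oH * oW), coli(K, (size_t)oH * oW);
  const bool hb = br.isNotNull();
  NumericVector brv, biv;
  if (hb) { brv = br.get(); biv = bi.get(); }
  for (int n = 0; n < N; ++n) {
    im2col_one(xr.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, colr);
    im2col_one(xi.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, coli);
    arma::mat yrn(yr.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW, F, false, true);
    arma::mat yin(yi.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW, F, false, true);
    yrn = colr.t() * Wr - coli.t() * Wi;
    yin = colr.t() * Wi + coli.t() * Wr;
    if (hb) for (int f = 0; f < F; ++f) { yrn.col(f) += brv[f]; yin.col(f) += biv[f]; }
    act_inplace(yr.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW * F, act);
    act_inplace(yi.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW * F, act);
  }
  return List::create(_["re"] = yr, _["im"] = yi);
}

static void col2im_one(const arma::mat& dcol, double* dxn, int H, int W, int C,
                       int kh, int kw, int ph, int pw, int oH, int oW) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dxn + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* dr = dcol.memptr() + r;
        for (int ow = 0; ow < oW; ++ow) {
          const int xw = ow + j - pw;
          if (xw < 0 || xw >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int xh = oh + i - ph;
            if (xh < 0 || xh >= H) continue;
            dxc[(size_t)xw * H + xh] += dr[(size_t)(ow * oH + oh) * dcol.n_rows];
          }
        }
      }
  }
}

// dyr/dyi are modified in place by the activation derivative (outr/outi are
// the forward outputs).
// [[Rcpp::export]]
List cconv2d_bwd_cpp(NumericVector xr, NumericVector xi,
                     NumericVector wr, NumericVector wi,
                     NumericVector dyr, NumericVector dyi,
                     int ph, int pw,
                     Nullable<NumericVector> outr = R_NilValue,
                     Nullable<NumericVector> outi = R_NilValue,
                     int act = 0, bool want_db = false) {
  IntegerVector xd = xr.attr("dim"), wd = wr.attr("dim"), yd = dyr.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int oH = yd[0], oW = yd[1];
  const int K = kh * kw * C;
  arma::mat Wr(const_cast<double*>(wr.begin()), K, F, false, true);
  arma::mat Wi(const_cast<double*>(wi.begin()), K, F, false, true);
  if (act != 0) {
    NumericVector ovr = outr.get(), ovi = outi.get();
    const R_xlen_t len = dyr.size();
    if (act == 1) {
      for (R_xlen_t q = 0; q < len; ++q) { if (ovr[q] <= 0) dyr[q] = 0; if (ovi[q] <= 0) dyi[q] = 0; }
    } else if (act == 2) {
      for (R_xlen_t q = 0; q < len; ++q) { dyr[q] *= ovr[q] * (1 - ovr[q]); dyi[q] *= ovi[q] * (1 - ovi[q]); }
    }
  }
  NumericVector dbr(F), dbi(F);
  if (want_db) {
    for (int n = 0; n < N; ++n)
      for (int f = 0; f < F; ++f) {
        const double* pr = dyr.begin() + ((size_t)n * F + f) * oH * oW;
        const double* pi = dyi.begin() + ((size_t)n * F + f) * oH * oW;
        double sr = 0, si = 0;
        for (int q = 0; q < oH * oW; ++q) { sr += pr[q]; si += pi[q]; }
        dbr[f] += sr; dbi[f] += si;
      }
  }
  NumericVector dxr(xr.size()), dxi(xr.size());
  dxr.attr("dim") = xd; dxi.attr("dim") = xd;
  NumericVector dwr(wr.size()), dwi(wr.size());
  dwr.attr("dim") = wd; dwi.attr("dim") = wd;
  arma::mat dWr(dwr.begin(), K, F, false, true), dWi(dwi.begin(), K, F, false, true);
  arma::mat colr(K, (size_t)oH * oW), coli(K, (size_t)oH * oW);
  arma::mat dcol(K, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col_one(xr.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, colr);
    im2col_one(xi.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW, coli);
    arma::mat dyrn(const_cast<double*>(dyr.begin()) + (size_t)n * oH * oW * F,
                   (size_t)oH * oW, F, false, true);
    arma::mat dyin(const_cast<double*>(dyi.begin()) + (size_t)n * oH * oW * F,
                   (size_t)oH * oW, F, false, true);
    dWr += colr * dyrn + coli * dyin;
    dWi += colr * dyin - coli * dyrn;
    dcol = Wr * dyrn.t() + Wi * dyin.t();
    col2im_one(dcol, dxr.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW);
    dcol = Wr * dyin.t() - Wi * dyrn.t();
    col2im_one(dcol, dxi.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, ph, pw, oH, oW);
  }
  return List::create(_["dxr"] = dxr, _["dxi"] = dxi, _["dwr"] = dwr,
                      _["dwi"] = dwi, _["dbr"] = dbr, _["dbi"] = dbi);
}
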