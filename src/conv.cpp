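// Compiled kernels for feature maps stored INTERNALLY as R arrays of dim
// (H, W, C, B): each channel plane is a contiguous H x W block (h fastest),
// which keeps convolution, layer norm and resampling cache-friendly.  The
// package's public API converts from/to the documented (B, C, H, W) order
// at the boundary.
//
// Convolution is stride 1 with "same" zero padding.  Weights have dim
// (kh, kw, cin_per_group, cout); bias is length cout.  The general path
// copies input planes into zero-padded buffers where every kernel tap is a
// uniform flat-index offset, so the convolution is kh*kw shifted GEMMs (a
// 1x1 kernel is a single zero-copy GEMM on strided matrix views).  The
// depthwise case (groups == cin == cout) takes a direct per-tap path.
#include <RcppArmadillo.h>
using namespace Rcpp;

// plane pointer for (c, b) in an (H, W, C, B) array
static inline const double* plane(const double* x, R_xlen_t c, R_xlen_t b,
                                  R_xlen_t H, R_xlen_t W, R_xlen_t C) {
  return x + H * W * (c + C * b);
}
static inline double* plane(double* x, R_xlen_t c, R_xlen_t b,
                            R_xlen_t H, R_xlen_t W, R_xlen_t C) {
  return x + H * W * (c + C * b);
}

// copy a contiguous H x W plane into the interior of a zeroed padded
// (Hp x Wp) buffer
static void pad_plane(const double* src, double* dst,
                      R_xlen_t H, R_xlen_t W, int ph, int pw) {
  R_xlen_t Hp = H + 2 * ph;
  for (R_xlen_t w = 0; w < W; ++w)
    std::copy(src + H * w, src + H * (w + 1), dst + ph + Hp * (pw + w));
}

// add / copy interior of padded buffer back into a contiguous plane
static void unpad_plane(const double* srcp, double* dst,
                        R_xlen_t H, R_xlen_t W, int ph, int pw, bool add) {
  R_xlen_t Hp = H + 2 * ph;
  for (R_xlen_t w = 0; w < W; ++w) {
    const double* s = srcp + ph + Hp * (pw + w);
    double* d = dst + H * w;
    if (add) for (R_xlen_t h = 0; h < H; ++h) d[h] += s[h];
    else     std::copy(s, s + H, d);
  }
}

// tap weight matrix (cing x coutg) for kernel position (ki, kj) of group g
static arma::mat tap_weights(const double* wts, int ki, int kj, int kh, int kw,
                             R_xlen_t cing, R_xlen_t coutg, int g) {
  arma::mat Wt(cing, coutg);
  R_xlen_t kk = (R_xlen_t)kh * kw;
  const double* base = wts + ki + kh * kj + kk * cing * coutg * g;
  for (R_xlen_t o = 0; o < coutg; ++o)
    for (R_xlen_t c = 0; c < cing; ++c)
      Wt(c, o) = base[kk * (c + cing * o)];
  return Wt;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector wts, IntegerVector wdim,
                             NumericVector bias, int groups) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int kh = wdim[0], kw = wdim[1];
  R_xlen_t cing = wdim[2], cout = wdim[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  R_xlen_t coutg = cout / groups;
  bool has_bias = bias.size() > 0;
  R_xlen_t P = H * W;
  NumericVector out(P * cout * B);
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t Hp = H + 2 * ph, Wp = W + 2 * pw, Np = Hp * Wp;

  if (groups == C && cout == C && cing == 1) {   // depthwise
    arma::vec xpl(Np);
    for (R_xlen_t b = 0; b < B; ++b)
      for (R_xlen_t c = 0; c < C; ++c) {
        xpl.zeros();
        pad_plane(plane(xp, c, b, H, W, C), xpl.memptr(), H, W, ph, pw);
        double* opl = plane(op, c, b, H, W, C);
        double bv = has_bias ? bias[c] : 0.0;
        std::fill(opl, opl + P, bv);
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            double wv = wts[ki + kh * kj + kh * kw * c];
            for (R_xlen_t w = 0; w < W; ++w) {
              const double* src = xpl.memptr() + ki + Hp * (kj + w);
              double* dst = opl + H * w;
              for (R_xlen_t h = 0; h < H; ++h) dst[h] += wv * src[h];
            }
          }
      }
    return out;
  }

  if (kh == 1 && kw == 1) {                      // pure GEMM, zero copy
    for (R_xlen_t b = 0; b < B; ++b)
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(plane(xp, g * cing, b, H, W, C)),
                          P, cing, false, true);
        arma::mat Wm(const_cast<double*>(wts.begin()) + cing * coutg * g,
                     cing, coutg, false, true);
        arma::mat O(plane(op, g * coutg, b, H, W, cout), P, coutg, false, true);
        O = X * Wm;
        if (has_bias)
          for (R_xlen_t o = 0; o < coutg; ++o) O.col(o) += bias[g * coutg + o];
      }
    return out;
  }

  arma::mat Xp(Np, cing), O(Np, coutg);
  for (R_xlen_t b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      Xp.zeros();
      for (R_xlen_t cl = 0; cl < cing; ++cl)
        pad_plane(plane(xp, g * cing + cl, b, H, W, C), Xp.colptr(cl),
                  H, W, ph, pw);
      O.zeros();
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          arma::mat Wt = tap_weights(wts.begin(), ki, kj, kh, kw, cing,
                                     coutg, g);
          R_xlen_t delta = (ki - ph) + Hp * (R_xlen_t)(kj - pw);
          R_xlen_t r0 = std::max((R_xlen_t)0, -delta);
          R_xlen_t r1 = Np - 1 - std::max((R_xlen_t)0, delta);
          O.rows(r0, r1) += Xp.rows(r0 + delta, r1 + delta) * Wt;
        }
      for (R_xlen_t o = 0; o < coutg; ++o) {
        if (has_bias) O.col(o) += bias[g * coutg + o];
        unpad_plane(O.colptr(o), plane(op, g * coutg + o, b, H, W, cout),
                    H, W, ph, pw, false);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector wts, IntegerVector wdim,
                    NumericVector gout, int groups, bool has_bias) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int kh = wdim[0], kw = wdim[1];
  R_xlen_t cing = wdim[2], cout = wdim[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  R_xlen_t coutg = cout / groups;
  R_xlen_t P = H * W;
  NumericVector gx(x.size());
  NumericVector gw(wts.size());
  NumericVector gb(has_bias ? cout : 0);
  const double* xp = x.begin();
  const double* gop = gout.begin();
  double* gxp = gx.begin();
  R_xlen_t Hp = H + 2 * ph, Wp = W + 2 * pw, Np = Hp * Wp;
  R_xlen_t kk = (R_xlen_t)kh * kw;

  if (groups == C && cout == C && cing == 1) {   // depthwise
    arma::vec xpl(Np), gxpl(Np);
    for (R_xlen_t b = 0; b < B; ++b)
      for (R_xlen_t c = 0; c < C; ++c) {
        xpl.zeros(); gxpl.zeros();
        pad_plane(plane(xp, c, b, H, W, C), xpl.memptr(), H, W, ph, pw);
        const double* gpl = plane(gop, c, b, H, W, C);
        if (has_bias) {
          double s = 0;
          for (R_xlen_t i = 0; i < P; ++i) s += gpl[i];
          gb[c] += s;
        }
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            R_xlen_t wi = ki + kh * kj + kk * c;
            double wv = wts[wi], acc = 0;
            for (R_xlen_t w = 0; w < W; ++w) {
              const double* gsrc = gpl + H * w;
              const double* xsrc = xpl.memptr() + ki + Hp * (kj + w);
              double* gdst = gxpl.memptr() + ki + Hp * (kj + w);
              for (R_xlen_t h = 0; h < H; ++h) {
                acc += gsrc[h] * xsrc[h];
                gdst[h] += gsrc[h] * wv;
              }
            }
            gw[wi] += acc;
          }
        unpad_plane(gxpl.memptr(), plane(gxp, c, b, H, W, C), H, W, ph, pw,
                    true);
      }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  if (kh == 1 && kw == 1) {                      // zero-copy GEMMs
    for (R_xlen_t b = 0; b < B; ++b)
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(plane(xp, g * cing, b, H, W, C)),
                          P, cing, false, true);
        const arma::mat G(const_cast<double*>(plane(gop, g * coutg, b, H, W, cout)),
                          P, coutg, false, true);
        arma::mat Wm(const_cast<double*>(wts.begin()) + cing * coutg * g,
                     cing, coutg, false, true);
        arma::mat Gw(gw.begin() + cing * coutg * g, cing, coutg, false, true);
        arma::mat GX(plane(gxp, g * cing, b, H, W, C), P, cing, false, true);
        Gw += X.t() * G;
        GX += G * Wm.t();
        if (has_bias)
          for (R_xlen_t o = 0; o < coutg; ++o)
            gb[g * coutg + o] += arma::accu(G.col(o));
      }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  arma::mat Xp(Np, cing), Gp(Np, coutg), gXp(Np, cing);
  for (R_xlen_t b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      Xp.zeros(); Gp.zeros();
      for (R_xlen_t cl = 0; cl < cing; ++cl)
        pad_plane(plane(xp, g * cing + cl, b, H, W, C), Xp.colptr(cl),
                  H, W, ph, pw);
      for (R_xlen_t o = 0; o < coutg; ++o) {
        pad_plane(plane(gop, g * coutg + o, b, H, W, cout), Gp.colptr(o),
                  H, W, ph, pw);
        if (has_bias) gb[g * coutg + o] += arma::accu(Gp.col(o));
      }
      gXp.zeros();
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          arma::mat Wt = tap_weights(wts.begin(), ki, kj, kh, kw, cing,
                                     coutg, g);
          R_xlen_t delta = (ki - ph) + Hp * (R_xlen_t)(kj - pw);
          R_xlen_t r0 = std::max((R_xlen_t)0, -delta);
          R_xlen_t r1 = Np - 1 - std::max((R_xlen_t)0, delta);
          arma::mat Gwt = Xp.rows(r0 + delta, r1 + delta).t() * Gp.rows(r0, r1);
          double* base = gw.begin() + ki + kh * kj + kk * cing * coutg * g;
          for (R_xlen_t o = 0; o < coutg; ++o)
            for (R_xlen_t c = 0; c < cing; ++c)
              base[kk * (c + cing * o)] += Gwt(c, o);
          gXp.rows(r0 + delta, r1 + delta) += Gp.rows(r0, r1) * Wt.t();
        }
      for (R_xlen_t cl = 0; cl < cing; ++cl)
        unpad_plane(gXp.colptr(cl), plane(gxp, g * cing + cl, b, H, W, C),
                    H, W, ph, pw, true);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// layer norm over channels at each (h, w, b) location; x is (H, W, C, B)
// [[Rcpp::export(name = ".cpp_ln_fwd")]]
List cpp_ln_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
                NumericVector beta, double eps) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t P = H * W;
  NumericVector y(x.size()), xn(x.size()), inv(P * B);
  const double* xp = x.begin();
  double* yp = y.begin(); double* np = xn.begin(); double* ip = inv.begin();
  std::vector<double> mu(P);
  for (R_xlen_t b = 0; b < B; ++b) {
    double* ib = ip + P * b;
    std::fill(mu.begin(), mu.end(), 0.0);
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* pl = plane(xp, c, b, H, W, C);
      for (R_xlen_t i = 0; i < P; ++i) mu[i] += pl[i];
    }
    for (R_xlen_t i = 0; i < P; ++i) mu[i] /= C;
    std::fill(ib, ib + P, 0.0);
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* pl = plane(xp, c, b, H, W, C);
      for (R_xlen_t i = 0; i < P; ++i) {
        double d = pl[i] - mu[i];
        ib[i] += d * d;
      }
    }
    for (R_xlen_t i = 0; i < P; ++i)
      ib[i] = 1.0 / std::sqrt(ib[i] / C + eps);
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* pl = plane(xp, c, b, H, W, C);
      double* npl = plane(np, c, b, H, W, C);
      double* ypl = plane(yp, c, b, H, W, C);
      double gc = gamma[c], bc = beta[c];
      for (R_xlen_t i = 0; i < P; ++i) {
        double n = (pl[i] - mu[i]) * ib[i];
        npl[i] = n;
        ypl[i] = n * gc + bc;
      }
    }
  }
  return List::create(_["y"] = y, _["xn"] = xn, _["inv"] = inv);
}

// [[Rcpp::export(name = ".cpp_ln_bwd")]]
List cpp_ln_bwd(NumericVector g, IntegerVector xdim, NumericVector xn,
                NumericVector inv, NumericVector gamma) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t P = H * W;
  NumericVector gx(g.size()), ggamma(C), gbeta(C);
  const double* gp = g.begin(); const double* np = xn.begin();
  const double* ip = inv.begin();
  double* gxp = gx.begin();
  std::vector<double> s1(P), s2(P);
  for (R_xlen_t b = 0; b < B; ++b) {
    const double* ib = ip + P * b;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* gpl = plane(gp, c, b, H, W, C);
      const double* npl = plane(np, c, b, H, W, C);
      double gc = gamma[c], sg = 0, sb = 0;
      for (R_xlen_t i = 0; i < P; ++i) {
        double gn = gpl[i] * gc;
        s1[i] += gn;
        s2[i] += gn * npl[i];
        sg += gpl[i] * npl[i];
        sb += gpl[i];
      }
      ggamma[c] += sg;
      gbeta[c] += sb;
    }
    for (R_xlen_t i = 0; i < P; ++i) { s1[i] /= C; s2[i] /= C; }
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* gpl = plane(gp, c, b, H, W, C);
      const double* npl = plane(np, c, b, H, W, C);
      double* gxpl = plane(gxp, c, b, H, W, C);
      double gc = gamma[c];
      for (R_xlen_t i = 0; i < P; ++i)
        gxpl[i] = (gpl[i] * gc - s1[i] - npl[i] * s2[i]) * ib[i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// bilinear 2x upsampling (align_corners = FALSE): (H,W,C,B) -> (2H,2W,C,B)
// [[Rcpp::export(name = ".cpp_up2_fwd")]]
NumericVector cpp_up2_fwd(NumericVector x, IntegerVector xdim) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t H2 = 2 * H, W2 = 2 * W;
  NumericVector y(H2 * W2 * C * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<R_xlen_t> i0(H2), i1(H2); std::vector<double> fh(H2);
  for (R_xlen_t o = 0; o < H2; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    double fl = std::floor(src);
    fh[o] = src - fl;
    i0[o] = std::min(std::max((R_xlen_t)fl, (R_xlen_t)0), H - 1);
    i1[o] = std::min(std::max((R_xlen_t)fl + 1, (R_xlen_t)0), H - 1);
  }
  for (R_xlen_t cb = 0; cb < C * B; ++cb) {
    const double* xpl = xp + H * W * cb;
    double* ypl = yp + H2 * W2 * cb;
    for (R_xlen_t w = 0; w < W2; ++w) {
      double srcw = (w + 0.5) / 2.0 - 0.5;
      double flw = std::floor(srcw);
      double fw = srcw - flw;
      R_xlen_t j0 = std::min(std::max((R_xlen_t)flw, (R_xlen_t)0), W - 1);
      R_xlen_t j1 = std::min(std::max((R_xlen_t)flw + 1, (R_xlen_t)0), W - 1);
      const double* c0 = xpl + H * j0;
      const double* c1 = xpl + H * j1;
      double* dst = ypl + H2 * w;
      for (R_xlen_t h = 0; h < H2; ++h) {
        double v0 = (1 - fh[h]) * c0[i0[h]] + fh[h] * c0[i1[h]];
        double v1 = (1 - fh[h]) * c1[i0[h]] + fh[h] * c1[i1[h]];
        dst[h] = (1 - fw) * v0 + fw * v1;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_up2_bwd")]]
NumericVector cpp_up2_bwd(NumericVector g, IntegerVector xdim) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t H2 = 2 * H, W2 = 2 * W;
  NumericVector gx(H * W * C * B);
  const double* gp = g.begin();
  double* xp = gx.begin();
  std::vector<R_xlen_t> i0(H2), i1(H2); std::vector<double> fh(H2);
  for (R_xlen_t o = 0; o < H2; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    double fl = std::floor(src);
    fh[o] = src - fl;
    i0[o] = std::min(std::max((R_xlen_t)fl, (R_xlen_t)0), H - 1);
    i1[o] = std::min(std::max((R_xlen_t)fl + 1, (R_xlen_t)0), H - 1);
  }
  for (R_xlen_t cb = 0; cb < C * B; ++cb) {
    const double* gpl = gp + H2 * W2 * cb;
    double* xpl = xp + H * W * cb;
    for (R_xlen_t w = 0; w < W2; ++w) {
      double srcw = (w + 0.5) / 2.0 - 0.5;
      double flw = std::floor(srcw);
      double fw = srcw - flw;
      R_xlen_t j0 = std::min(std::max((R_xlen_t)flw, (R_xlen_t)0), W - 1);
      R_xlen_t j1 = std::min(std::max((R_xlen_t)flw + 1, (R_xlen_t)0), W - 1);
      double* c0 = xpl + H * j0;
      double* c1 = xpl + H * j1;
      const double* src = gpl + H2 * w;
      for (R_xlen_t h = 0; h < H2; ++h) {
        double v = src[h];
        c0[i0[h]] += (1 - fw) * (1 - fh[h]) * v;
        c0[i1[h]] += (1 - fw) * fh[h] * v;
        c1[i0[h]] += fw * (1 - fh[h]) * v;
        c1[i1[h]] += fw * fh[h] * v;
      }
    }
  }
  return gx;
}

// 2x2 max pooling with argmax (0..3 = which of the 2x2 cell, h-major):
// (H,W,C,B) -> (H/2, W/2, C, B)
// [[Rcpp::export(name = ".cpp_mp2_fwd")]]
List cpp_mp2_fwd(NumericVector x, IntegerVector xdim) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * B);
  IntegerVector which(Ho * Wo * C * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* wp = which.begin();
  for (R_xlen_t cb = 0; cb < C * B; ++cb) {
    const double* xpl = xp + H * W * cb;
    double* ypl = yp + Ho * Wo * cb;
    int* wpl = wp + Ho * Wo * cb;
    for (R_xlen_t w = 0; w < Wo; ++w) {
      const double* c0 = xpl + H * (2 * w);
      const double* c1 = xpl + H * (2 * w + 1);
      for (R_xlen_t h = 0; h < Ho; ++h) {
        double v0 = c0[2 * h], v1 = c0[2 * h + 1];
        double v2 = c1[2 * h], v3 = c1[2 * h + 1];
        double m = v0; int a = 0;
        if (v1 > m) { m = v1; a = 1; }
        if (v2 > m) { m = v2; a = 2; }
        if (v3 > m) { m = v3; a = 3; }
        ypl[h + Ho * w] = m;
        wpl[h + Ho * w] = a;
      }
    }
  }
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export(name = ".cpp_mp2_bwd")]]
NumericVector cpp_mp2_bwd(NumericVector g, IntegerVector which,
                          IntegerVector xdim) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  R_xlen_t Ho = H / 2, Wo = W / 2;
  NumericVector gx(H * W * C * B);
  const double* gp = g.begin();
  const int* wp = which.begin();
  double* xp = gx.begin();
  for (R_xlen_t cb = 0; cb < C * B; ++cb) {
    const double* gpl = gp + Ho * Wo * cb;
    const int* wpl = wp + Ho * Wo * cb;
    double* xpl = xp + H * W * cb;
    for (R_xlen_t w = 0; w < Wo; ++w) {
      for (R_xlen_t h = 0; h < Ho; ++h) {
        int a = wpl[h + Ho * w];
        R_xlen_t hh = 2 * h + (a & 1);
        R_xlen_t ww = 2 * w + (a >> 1);
        xpl[hh + H * ww] = gpl[h + Ho * w];
      }
    }
  }
  return gx;
}

// axial shift of contiguous channel partitions with zero fill on (H,W,C,B);
// offsets is an integer vector of per-channel offsets (already expanded),
// axis 0 = height (dim 1), 1 = width (dim 2)
// [[Rcpp::export(name = ".cpp_shift_fwd")]]
NumericVector cpp_shift_fwd(NumericVector x, IntegerVector xdim,
                            IntegerVector offsets, int axis) {
  R_xlen_t H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t b = 0; b < B; ++b)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* xpl = xp + H * W * (c + C * b);
      double* ypl = yp + H * W * (c + C * b);
      R_xlen_t o = offsets[c];
      if (axis == 0) {               // shift along h within each column
        if (o >= H || -o >= H) continue;
        for (R_xlen_t w = 0; w < W; ++w) {
          const double* src = xpl + H * w;
          double* dst = ypl + H * w;
          if (o >= 0) std::copy(src, src + (H - o), dst + o);
          else        std::copy(src - o, src + H, dst);
        }
      } else {                       // shift whole columns
        if (o >= W || -o >= W) continue;
        if (o >= 0) std::copy(xpl, xpl + H * (W - o), ypl + H * o);
        else        std::copy(xpl - H * o, xpl + H * W, ypl);
      }
    }
  return y;
}
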