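// Low-level tensor kernels for the segmentation network.
//
// Internal activation layout: dim = c(H, W, C, N) — each image is a block of
// C contiguous (H x W) channel planes, so convolutions run as BLAS products
// on zero-copy (H*W x C) views and spatial kernels stream each plane in
// order. (The exported R API presents batches as (N, C, H, W); the R side
// converts at that boundary only.)
// Convolutions are stride-1 with zero padding; spatial downsampling in the
// network is done by pooling, never by strided convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// weight layout stays (Cout, Cin/groups, kh, kw) as on the R side
static inline long widx(long co, long c, long ki, long kj,
                        long Cout, long Cg, long kh) {
  return co + Cout * (c + Cg * (ki + kh * kj));
}

// im2col on channel planes [c0, c0+Cg) of one image:
// col is (Cg*kh*kw) x (Ho*Wo), column j = ho + Ho*wo, row r = (c*kw + kj)*kh + ki
static void im2col_planes(const double *xt, long c0, long Cg,
                          long H, long W, long kh, long kw, long pad, long dil,
                          long Ho, long Wo, arma::mat &col) {
  col.zeros();
  for (long c = 0; c < Cg; ++c) {
    const double *plane = xt + H * W * (c0 + c);
    for (long kj = 0; kj < kw; ++kj)
      for (long ki = 0; ki < kh; ++ki) {
        long r = (c * kw + kj) * kh + ki;
        for (long wo = 0; wo < Wo; ++wo) {
          long w = wo - pad + dil * kj;
          if (w < 0 || w >= W) continue;
          long h0 = -pad + dil * ki;          // source h at ho = 0
          long holo = std::max((long)0, -h0);
          long hohi = std::min(Ho, H - h0);
          const double *src = plane + h0 + holo + H * w;
          double *dst = col.colptr(Ho * wo) + r;
          for (long ho = holo; ho < hohi; ++ho)
            dst[(size_t)ho * col.n_rows] = src[ho - holo];
        }
      }
  }
}

static void col2im_planes_add(double *xt, const arma::mat &col, long c0, long Cg,
                              long H, long W, long kh, long kw, long pad,
                              long dil, long Ho, long Wo) {
  for (long c = 0; c < Cg; ++c) {
    double *plane = xt + H * W * (c0 + c);
    for (long kj = 0; kj < kw; ++kj)
      for (long ki = 0; ki < kh; ++ki) {
        long r = (c * kw + kj) * kh + ki;
        for (long wo = 0; wo < Wo; ++wo) {
          long w = wo - pad + dil * kj;
          if (w < 0 || w >= W) continue;
          long h0 = -pad + dil * ki;
          long holo = std::max((long)0, -h0);
          long hohi = std::min(Ho, H - h0);
          double *dst = plane + h0 + holo + H * w;
          const double *src = col.colptr(Ho * wo) + r;
          for (long ho = holo; ho < hohi; ++ho)
            dst[ho - holo] += src[(size_t)ho * col.n_rows];
        }
      }
  }
}

// pack group weights as (Cog x R) matching im2col row order
static void pack_weights(const double *w, arma::mat &wm, long g, long Cog,
                         long Cout, long Cg, long kh, long kw) {
  for (long co = 0; co < Cog; ++co)
    for (long c = 0; c < Cg; ++c)
      for (long kj = 0; kj < kw; ++kj)
        for (long ki = 0; ki < kh; ++ki)
          wm(co, (c * kw + kj) * kh + ki) =
            w[widx(g * Cog + co, c, ki, kj, Cout, Cg, kh)];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int pad, int dil, int groups) {
  IntegerVector dx_ = dims4(x);
  IntegerVector dw_ = dims4(w);
  long H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  long Cout = dw_[0], Cg = dw_[1], kh = dw_[2], kw = dw_[3];
  if (C != Cg * groups) stop("conv2d: input channels do not match weights/groups");
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  long Ho = H + 2 * (long)pad - (long)dil * (kh - 1);
  long Wo = W + 2 * (long)pad - (long)dil * (kw - 1);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  long Cog = Cout / groups, R = Cg * kh * kw, J = Ho * Wo;

  NumericVector y(N * Cout * J);
  y.attr("dim") = IntegerVector::create((int)Ho, (int)Wo, (int)Cout, (int)N);
  std::vector<arma::mat> wms(groups, arma::mat(Cog, R));
  for (long g = 0; g < groups; ++g)
    pack_weights(w.begin(), wms[g], g, Cog, Cout, Cg, kh, kw);

  bool one_by_one = (kh == 1 && kw == 1 && pad == 0);
  bool depthwise = (Cg == 1 && Cog == 1);
  arma::mat col;
  if (!one_by_one && !depthwise) col.set_size(R, J);

  for (long n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * C * H * W;
    double *yn = y.begin() + n * Cout * J;
    if (one_by_one) {
      const arma::mat X(const_cast<double *>(xn), H * W, C, false, true);
      for (long g = 0; g < groups; ++g) {
        arma::mat out(yn + g * Cog * J, J, Cog, false, true);
        out = X.cols(g * Cg, (g + 1) * Cg - 1) * wms[g].t();   // (J x Cog)
      }
    } else if (depthwise) {
      for (long c = 0; c < C; ++c) {
        const double *plane = xn + H * W * c;
        double *yplane = yn + J * c;
        std::fill(yplane, yplane + J, 0.0);
        for (long kj = 0; kj < kw; ++kj)
          for (long ki = 0; ki < kh; ++ki) {
            double wv = w[widx(c, 0, ki, kj, Cout, 1, kh)];
            long h0 = -pad + dil * ki;
            long holo = std::max((long)0, -h0);
            long hohi = std::min(Ho, H - h0);
            for (long wo = 0; wo < Wo; ++wo) {
              long ws = wo - pad + dil * kj;
              if (ws < 0 || ws >= W) continue;
              const double *src = plane + h0 + holo + H * ws;
              double *dst = yplane + holo + Ho * wo;
              for (long ho = 0; ho < hohi - holo; ++ho) dst[ho] += wv * src[ho];
            }
          }
      }
    } else {
      for (long g = 0; g < groups; ++g) {
        im2col_planes(xn, g * Cg, Cg, H, W, kh, kw, pad, dil, Ho, Wo, col);
        arma::mat outT(yn + g * Cog * J, J, Cog, false, true);
        outT = col.t() * wms[g].t();                            // (J x Cog)
      }
    }
    for (long co = 0; co < Cout; ++co) {                        // bias
      double bias = b[co];
      double *p = yn + co * J;
      for (long j = 0; j < J; ++j) p[j] += bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int pad, int dil, int groups) {
  IntegerVector dx_ = dims4(x), dw_ = dims4(w), dy_ = dims4(dy);
  long H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  long Cout = dw_[0], Cg = dw_[1], kh = dw_[2], kw = dw_[3];
  long Ho = dy_[0], Wo = dy_[1];
  long Cog = Cout / groups, R = Cg * kh * kw, J = Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = dx_;
  NumericVector dw(w.size());
  dw.attr("dim") = dw_;
  NumericVector db(Cout);
  arma::mat col;
  std::vector<arma::mat> wms(groups, arma::mat(Cog, R));
  std::vector<arma::mat> dwms(groups, arma::mat(Cog, R, arma::fill::zeros));
  for (long g = 0; g < groups; ++g)
    pack_weights(w.begin(), wms[g], g, Cog, Cout, Cg, kh, kw);

  bool one_by_one = (kh == 1 && kw == 1 && pad == 0);
  bool depthwise = (Cg == 1 && Cog == 1);
  if (!one_by_one && !depthwise) col.set_size(R, J);

  for (long n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * C * H * W;
    double *dxn = dx.begin() + n * C * H * W;
    const double *gyn = dy.begin() + n * Cout * J;
    for (long co = 0; co < Cout; ++co) {
      const double *p = gyn + co * J;
      double acc = 0;
      for (long j = 0; j < J; ++j) acc += p[j];
      db[co] += acc;
    }
    if (one_by_one) {
      const arma::mat X(const_cast<double *>(xn), H * W, C, false, true);
      arma::mat dX(dxn, H * W, C, false, true);
      const arma::mat GY(const_cast<double *>(gyn), J, Cout, false, true);
      for (long g = 0; g < groups; ++g) {
        arma::mat gg = GY.cols(g * Cog, (g + 1) * Cog - 1);
        dwms[g] += gg.t() * X.cols(g * Cg, (g + 1) * Cg - 1);
        dX.cols(g * Cg, (g + 1) * Cg - 1) = gg * wms[g];
      }
    } else if (depthwise) {
      for (long c = 0; c < C; ++c) {
        const double *plane = xn + H * W * c;
        double *dplane = dxn + H * W * c;
        const double *gplane = gyn + J * c;
        for (long kj = 0; kj < kw; ++kj)
          for (long ki = 0; ki < kh; ++ki) {
            double wv = w[widx(c, 0, ki, kj, Cout, 1, kh)];
            double dwv = 0;
            long h0 = -pad + dil * ki;
            long holo = std::max((long)0, -h0);
            long hohi = std::min(Ho, H - h0);
            for (long wo = 0; wo < Wo; ++wo) {
              long ws = wo - pad + dil * kj;
              if (ws < 0 || ws >= W) continue;
              const double *xp = plane + h0 + holo + H * ws;
              double *dxp = dplane + h0 + holo + H * ws;
              const double *gp = gplane + holo + Ho * wo;
              long len = hohi - holo;
              for (long ho = 0; ho < len; ++ho) {
                dwv += gp[ho] * xp[ho];
                dxp[ho] += wv * gp[ho];
              }
            }
            dw[widx(c, 0, ki, kj, Cout, 1, kh)] += dwv;
          }
      }
    } else {
      for (long g = 0; g < groups; ++g) {
        const arma::mat gg(const_cast<double *>(gyn) + g * Cog * J, J, Cog,
                           false, true);
        im2col_planes(xn, g * Cg, Cg, H, W, kh, kw, pad, dil, Ho, Wo, col);
        dwms[g] += gg.t() * col.t();
        arma::mat dcol = wms[g].t() * gg.t();                   // (R x J)
        col2im_planes_add(dxn, dcol, g * Cg, Cg, H, W, kh, kw, pad, dil,
                          Ho, Wo);
      }
    }
  }
  if (!depthwise)                            // depthwise wrote dw directly
    for (long g = 0; g < groups; ++g)
      for (long co = 0; co < Cog; ++co)
        for (long c = 0; c < Cg; ++c)
          for (long kj = 0; kj < kw; ++kj)
            for (long ki = 0; ki < kh; ++ki)
              dw[widx(g * Cog + co, c, ki, kj, Cout, Cg, kh)] =
                dwms[g](co, (c * kw + kj) * kh + ki);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; returns pooled values and 0-based argmax offsets.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector d = dims4(x);
  long H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool: H and W must be even");
  long Ho = H / 2, Wo = W / 2, P = C * N;
  NumericVector y(P * Ho * Wo);
  y.attr("dim") = IntegerVector::create((int)Ho, (int)Wo, d[2], d[3]);
  IntegerVector arg(y.size());
  for (long p = 0; p < P; ++p) {
    const double *plane = x.begin() + p * H * W;
    long off = p * H * W;
    double *yp = y.begin() + p * Ho * Wo;
    int *ap = arg.begin() + p * Ho * Wo;
    for (long w = 0; w < Wo; ++w)
      for (long h = 0; h < Ho; ++h) {
        long i00 = 2 * h + H * (2 * w);
        long i10 = i00 + 1, i01 = i00 + H, i11 = i00 + H + 1;
        double v = plane[i00];
        long bi = i00;
        if (plane[i10] > v) { v = plane[i10]; bi = i10; }
        if (plane[i01] > v) { v = plane[i01]; bi = i01; }
        if (plane[i11] > v) { v = plane[i11]; bi = i11; }
        yp[h + Ho * w] = v;
        ap[h + Ho * w] = (int)(off + bi);
      }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector arg,
                               IntegerVector xdim) {
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[arg[i]] += dy[i];
  return dx;
}

// non-overlapping r x r average pooling
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int r) {
  IntegerVector d = dims4(x);
  long H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % r || W % r) stop("avgpool: H and W must be divisible by the rate");
  long Ho = H / r, Wo = W / r, P = C * N;
  NumericVector y(P * Ho * Wo);
  y.attr("dim") = IntegerVector::create((int)Ho, (int)Wo, d[2], d[3]);
  double inv = 1.0 / (r * (double)r);
  for (long p = 0; p < P; ++p) {
    const double *plane = x.begin() + p * H * W;
    double *yp = y.begin() + p * Ho * Wo;
    for (long w = 0; w < Wo; ++w)
      for (long h = 0; h < Ho; ++h) {
        double s = 0;
        for (long dw2 = 0; dw2 < r; ++dw2) {
          const double *col = plane + r * h + H * (r * w + dw2);
          for (long dh = 0; dh < r; ++dh) s += col[dh];
        }
        yp[h + Ho * w] = s * inv;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, int r, IntegerVector xdim) {
  long H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx(H * W * C * N);
  dx.attr("dim") = xdim;
  long Ho = H / r, Wo = W / r, P = C * N;
  double inv = 1.0 / (r * (double)r);
  for (long p = 0; p < P; ++p) {
    const double *gp = dy.begin() + p * Ho * Wo;
    double *plane = dx.begin() + p * H * W;
    for (long w = 0; w < Wo; ++w)
      for (long h = 0; h < Ho; ++h) {
        double g = gp[h + Ho * w] * inv;
        for (long dw2 = 0; dw2 < r; ++dw2) {
          double *col = plane + r * h + H * (r * w + dw2);
          for (long dh = 0; dh < r; ++dh) col[dh] += g;
        }
      }
  }
  return dx;
}

// Bilinear resize with half-pixel centers (source = (dst+0.5)*scale - 0.5,
// clamped), the convention used throughout the package.
static inline void bl_coeff(long o, long So, long Si, long &i0, long &i1,
                            double &f) {
  double s = (o + 0.5) * (double)Si / So - 0.5;
  if (s < 0) s = 0;
  if (s > Si - 1) s = Si - 1;
  i0 = (long)std::floor(s);
  i1 = std::min(i0 + 1, Si - 1);
  f = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector d = dims4(x);
  long H = d[0], W = d[1], C = d[2], N = d[3], P = C * N;
  NumericVector y(P * (long)Ho * Wo);
  y.attr("dim") = IntegerVector::create(Ho, Wo, d[2], d[3]);
  std::vector<long> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (long h = 0; h < Ho; ++h) bl_coeff(h, Ho, H, h0[h], h1[h], fh[h]);
  for (long w = 0; w < Wo; ++w) bl_coeff(w, Wo, W, w0[w], w1[w], fw[w]);
  for (long p = 0; p < P; ++p) {
    const double *plane = x.begin() + p * H * W;
    double *yp = y.begin() + p * (long)Ho * Wo;
    for (long w = 0; w < Wo; ++w) {
      const double *c0 = plane + H * w0[w];
      const double *c1 = plane + H * w1[w];
      double g = fw[w];
      for (long h = 0; h < Ho; ++h) {
        double a = c0[h0[h]] * (1 - fh[h]) + c0[h1[h]] * fh[h];
        double b = c1[h0[h]] * (1 - fh[h]) + c1[h1[h]] * fh[h];
        yp[h + (long)Ho * w] = a * (1 - g) + b * g;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector d = dims4(dy);
  long Ho = d[0], Wo = d[1], C = d[2], N = d[3], P = C * N;
  NumericVector dx(P * (long)H * W);
  dx.attr("dim") = IntegerVector::create(H, W, d[2], d[3]);
  std::vector<long> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (long h = 0; h < Ho; ++h) bl_coeff(h, Ho, H, h0[h], h1[h], fh[h]);
  for (long w = 0; w < Wo; ++w) bl_coeff(w, Wo, W, w0[w], w1[w], fw[w]);
  for (long p = 0; p < P; ++p) {
    const double *gp = dy.begin() + p * Ho * Wo;
    double *plane = dx.begin() + p * (long)H * W;
    for (long w = 0; w < Wo; ++w) {
      double *c0 = plane + H * w0[w];
      double *c1 = plane + H * w1[w];
      double gw2 = fw[w];
      for (long h = 0; h < Ho; ++h) {
        double g = gp[h + Ho * w];
        c0[h0[h]] += g * (1 - fh[h]) * (1 - gw2);
        c0[h1[h]] += g * fh[h] * (1 - gw2);
        c1[h0[h]] += g * (1 - fh[h]) * gw2;
        c1[h1[h]] += g * fh[h] * gw2;
      }
    }
  }
  return dx;
}

// Nearest-neighbour resize of a plain H x W matrix (used for masks).
// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest_mat(NumericMatrix x, int Ho, int Wo) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(Ho, Wo);
  for (int w = 0; w < Wo; ++w) {
    int sw = std::min((int)std::floor((w + 0.5) * (double)W / Wo), W - 1);
    for (int h = 0; h < Ho; ++h) {
      int sh = std::min((int)std::floor((h + 0.5) * (double)H / Ho), H - 1);
      y(h, w) = x(sh, sw);
    }
  }
  return y;
}

// For every pixel, the Euclidean distance to the nearest foreground pixel of
// a binary mask and that pixel's 0-based linear index (column-major). Exact
// brute force over foreground pixels; masks here are small (<= a few hundred
// pixels square). Used by the weighted F-measure's error propagation.
// [[Rcpp::export]]
List cpp_nearest_fg(NumericMatrix gt) {
  int H = gt.nrow(), W = gt.ncol();
  std::vector<int> fh, fw;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      if (gt(h, w) > 0.5) { fh.push_back(h); fw.push_back(w); }
  NumericMatrix dist(H, W);
  IntegerMatrix idx(H, W);
  if (fh.empty()) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(idx.begin(), idx.end(), NA_INTEGER);
    return List::create(_["dist"] = dist, _["idx"] = idx);
  }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double best = R_PosInf;
      int bi = 0;
      for (size_t k = 0; k < fh.size(); ++k) {
        double dh = h - fh[k], dw2 = w - fw[k];
        double d2 = dh * dh + dw2 * dw2;
        if (d2 < best) { best = d2; bi = fh[k] + H * fw[k]; }
      }
      dist(h, w) = std::sqrt(best);
      idx(h, w) = bi;
    }
  return List::create(_["dist"] = dist, _["idx"] = idx);
}

// ---- batch norm and ReLU helpers (hot path; avoids R temporaries) ----

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector d = dims4(x);
  long HW = (long)d[0] * d[1], C = d[2], N = d[3];
  NumericVector mean(C), var(C);
  for (long n = 0; n < N; ++n)
    for (long c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + C * n);
      double s = 0, s2 = 0;
      for (long j = 0; j < HW; ++j) { s += p[j]; s2 += p[j] * p[j]; }
      mean[c] += s;
      var[c] += s2;
    }
  double M = (double)HW * N;
  for (long c = 0; c < C; ++c) {
    mean[c] /= M;
    var[c] = var[c] / M - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector scale,
                           NumericVector shift) {
  IntegerVector d = dims4(x);
  long HW = (long)d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (long n = 0; n < N; ++n)
    for (long c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + C * n);
      double *q = y.begin() + HW * (c + C * n);
      double a = scale[c], b = shift[c];
      for (long j = 0; j < HW; ++j) q[j] = a * p[j] + b;
    }
  return y;
}

// training-mode backward: given x, incoming grad g, gamma, batch mu and
// 1/sqrt(var+eps), returns dx, dgamma, dbeta
// [[Rcpp::export]]
List cpp_bn_bwd_train(NumericVector x, NumericVector g, NumericVector gamma,
                      NumericVector mu, NumericVector ivar) {
  IntegerVector d = dims4(x);
  long HW = (long)d[0] * d[1], C = d[2], N = d[3];
  double M = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = d;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (long n = 0; n < N; ++n)
    for (long c = 0; c < C; ++c) {
      const double *px = x.begin() + HW * (c + C * n);
      const double *pg = g.begin() + HW * (c + C * n);
      double m = mu[c], iv = ivar[c];
      double a = 0, b = 0;
      for (long j = 0; j < HW; ++j) {
        a += pg[j];
        b += pg[j] * (px[j] - m) * iv;
      }
      s1[c] += a;                             // sum g
      s2[c] += b;                             // sum g * xhat
    }
  for (long c = 0; c < C; ++c) { dbeta[c] = s1[c]; dgamma[c] = s2[c]; }
  for (long n = 0; n < N; ++n)
    for (long c = 0; c < C; ++c) {
      const double *px = x.begin() + HW * (c + C * n);
      const double *pg = g.begin() + HW * (c + C * n);
      double *pd = dx.begin() + HW * (c + C * n);
      double m = mu[c], iv = ivar[c], ga = gamma[c];
      double t1 = s1[c] / M, t2 = s2[c] / M;
      for (long j = 0; j < HW; ++j) {
        double xhat = (px[j] - m) * iv;
        pd[j] = ga * iv * (pg[j] - t1 - xhat * t2);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// eval-mode backward sums (dgamma, dbeta) for fixed running stats
// [[Rcpp::export]]
List cpp_bn_bwd_eval(NumericVector x, NumericVector g, NumericVector mu,
                     NumericVector ivar) {
  IntegerVector d = dims4(x);
  long HW = (long)d[0] * d[1], C = d[2], N = d[3];
  NumericVector dgamma(C), dbeta(C);
  for (long n = 0; n < N; ++n)
    for (long c = 0; c < C; ++c) {
      const double *px = x.begin() + HW * (c + C * n);
      const double *pg = g.begin() + HW * (c + C * n);
      double m = mu[c], iv = ivar[c], a = 0, b = 0;
      for (long j = 0; j < HW; ++j) {
        a += pg[j];
        b += pg[j] * (px[j] - m) * iv;
      }
      dbeta[c] += a;
      dgamma[c] += b;
    }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector x) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) dx[i] = x[i] > 0 ? g[i] : 0;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return y;
}
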