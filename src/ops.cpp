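// Low-level numerical kernels for the segmentation network.
//
// Array conventions (match the R side):
//   images / feature maps: numeric array [H, W, C], column-major, H fastest;
//   sampling grids: normalized align-corners coordinates, (-1,-1) = center of
//   the top-left pixel, (+1,+1) = center of the bottom-right pixel.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold x [H,W,C] into a [k*k*C, Ho*Wo] matrix. Column j corresponds to the
// output pixel (ho, wo) with j = ho + Ho*wo; row r = kh + k*kw + k*k*c.
// Out-of-range input pixels contribute zero.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericMatrix cols(k * k * C, Ho * Wo);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *col = pc + (std::size_t)(ho + Ho * wo) * nrow;
      for (int c = 0; c < C; ++c) {
        const double *plane = px + (std::size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = plane[hi + (std::size_t)H * wi];
            col[kh + k * kw + k * k * c] = v;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add columns back into an [H,W,C] array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector x((std::size_t)H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *col = pc + (std::size_t)(ho + Ho * wo) * nrow;
      for (int c = 0; c < C; ++c) {
        double *plane = px + (std::size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            plane[hi + (std::size_t)H * wi] += col[kh + k * kw + k * k * c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Depthwise (per-channel) convolution, filter w [k,k,C].
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, int H, int W, int C,
                            NumericVector w, int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((std::size_t)Ho * Wo * C);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (std::size_t)c * H * W;
    const double *ker = pw + (std::size_t)c * k * k;
    double *out = py + (std::size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            acc += plane[hi + (std::size_t)H * wi] * ker[kh + k * kw];
          }
        }
        out[ho + (std::size_t)Ho * wo] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, int H, int W, int C,
                   NumericVector w, int k, int stride, int pad,
                   NumericVector gy) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector gx((std::size_t)H * W * C), gw((std::size_t)k * k * C);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (std::size_t)c * H * W;
    const double *ker = pw + (std::size_t)c * k * k;
    const double *g = pg + (std::size_t)c * Ho * Wo;
    double *gplane = pgx + (std::size_t)c * H * W;
    double *gker = pgw + (std::size_t)c * k * k;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double gv = g[ho + (std::size_t)Ho * wo];
        if (gv == 0.0) continue;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            gplane[hi + (std::size_t)H * wi] += gv * ker[kh + k * kw];
            gker[kh + k * kw] += gv * plane[hi + (std::size_t)H * wi];
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  gw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

static inline double to_col(double xn, int W) {
  double c = (xn + 1.0) * 0.5 * (W - 1);
  // snap coordinates within one ulp-scale tolerance of a pixel center so
  // that exact transforms (e.g. the identity) reproduce pixels bitwise
  const double r = std::nearbyint(c);
  if (std::fabs(c - r) < 1e-9) c = r;
  return c;
}

// Bilinear sampling with zero padding outside the source (the truncated
// max(0, 1-|.|) kernel). img [H,W,C]; gx, gy length Hp*Wp in normalized
// coordinates; output [Hp,Wp,C] with the same (h fastest) pixel order as gx.
// [[Rcpp::export]]
NumericVector cpp_gs_fw(NumericVector img, int H, int W, int C,
                        NumericVector gx, NumericVector gy, int Hp, int Wp) {
  const int n = Hp * Wp;
  NumericVector out((std::size_t)n * C);
  const double *pi = img.begin();
  double *po = out.begin();
  for (int j = 0; j < n; ++j) {
    const double cx = to_col(gx[j], W), cy = to_col(gy[j], H);
    const int c0 = (int)std::floor(cx), r0 = (int)std::floor(cy);
    const double fx = cx - c0, fy = cy - r0;
    const double w00 = (1 - fx) * (1 - fy), w01 = fx * (1 - fy);
    const double w10 = (1 - fx) * fy, w11 = fx * fy;
    const bool c0ok = c0 >= 0 && c0 < W, c1ok = c0 + 1 >= 0 && c0 + 1 < W;
    const bool r0ok = r0 >= 0 && r0 < H, r1ok = r0 + 1 >= 0 && r0 + 1 < H;
    for (int c = 0; c < C; ++c) {
      const double *plane = pi + (std::size_t)c * H * W;
      double v = 0.0;
      if (r0ok && c0ok) v += w00 * plane[r0 + (std::size_t)H * c0];
      if (r0ok && c1ok) v += w01 * plane[r0 + (std::size_t)H * (c0 + 1)];
      if (r1ok && c0ok) v += w10 * plane[(r0 + 1) + (std::size_t)H * c0];
      if (r1ok && c1ok) v += w11 * plane[(r0 + 1) + (std::size_t)H * (c0 + 1)];
      po[j + (std::size_t)n * c] = v;
    }
  }
  out.attr("dim") = IntegerVector::create(Hp, Wp, C);
  return out;
}

// Backward of cpp_gs_fw: gradients w.r.t. the source image and the normalized
// grid coordinates.
// [[Rcpp::export]]
List cpp_gs_bw(NumericVector img, int H, int W, int C,
               NumericVector gx, NumericVector gy, int Hp, int Wp,
               NumericVector gout) {
  const int n = Hp * Wp;
  NumericVector gimg((std::size_t)H * W * C), ggx(n), ggy(n);
  const double *pi = img.begin(), *pg = gout.begin();
  double *pgi = gimg.begin();
  const double sx = 0.5 * (W - 1), sy = 0.5 * (H - 1);
  for (int j = 0; j < n; ++j) {
    const double cx = to_col(gx[j], W), cy = to_col(gy[j], H);
    const int c0 = (int)std::floor(cx), r0 = (int)std::floor(cy);
    const double fx = cx - c0, fy = cy - r0;
    const bool c0ok = c0 >= 0 && c0 < W, c1ok = c0 + 1 >= 0 && c0 + 1 < W;
    const bool r0ok = r0 >= 0 && r0 < H, r1ok = r0 + 1 >= 0 && r0 + 1 < H;
    double dx = 0.0, dy = 0.0;
    for (int c = 0; c < C; ++c) {
      const double g = pg[j + (std::size_t)n * c];
      if (g == 0.0) continue;
      const double *plane = pi + (std::size_t)c * H * W;
      double *gplane = pgi + (std::size_t)c * H * W;
      double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
      if (r0ok && c0ok) v00 = plane[r0 + (std::size_t)H * c0];
      if (r0ok && c1ok) v01 = plane[r0 + (std::size_t)H * (c0 + 1)];
      if (r1ok && c0ok) v10 = plane[(r0 + 1) + (std::size_t)H * c0];
      if (r1ok && c1ok) v11 = plane[(r0 + 1) + (std::size_t)H * (c0 + 1)];
      if (r0ok && c0ok) gplane[r0 + (std::size_t)H * c0] += g * (1 - fx) * (1 - fy);
      if (r0ok && c1ok) gplane[r0 + (std::size_t)H * (c0 + 1)] += g * fx * (1 - fy);
      if (r1ok && c0ok) gplane[(r0 + 1) + (std::size_t)H * c0] += g * (1 - fx) * fy;
      if (r1ok && c1ok) gplane[(r0 + 1) + (std::size_t)H * (c0 + 1)] += g * fx * fy;
      dx += g * ((1 - fy) * (v01 - v00) + fy * (v11 - v10));
      dy += g * ((1 - fx) * (v10 - v00) + fx * (v11 - v01));
    }
    ggx[j] = dx * sx;  // chain through cx = (gx+1)/2*(W-1)
    ggy[j] = dy * sy;
  }
  gimg.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["gimg"] = gimg, _["ggx"] = ggx, _["ggy"] = ggy);
}

// Nearest-neighbour sampling of an integer label map; out-of-range -> fill.
// [[Rcpp::export]]
IntegerVector cpp_gs_nearest(IntegerMatrix mask, NumericVector gx,
                             NumericVector gy, int Hp, int Wp, int fill) {
  const int H = mask.nrow(), W = mask.ncol(), n = Hp * Wp;
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    const int cc = (int)std::lround(to_col(gx[j], W));
    const int rr = (int)std::lround(to_col(gy[j], H));
    out[j] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? mask(rr, cc) : fill;
  }
  out.attr("dim") = IntegerVector::create(Hp, Wp);
  return out;
}

static inline double cubic_w(double t) {
  // Catmull-Rom (a = -0.5) interpolation kernel
  const double a = -0.5, at = std::fabs(t);
  if (at <= 1.0) return ((a + 2) * at - (a + 3)) * at * at + 1;
  if (at < 2.0) return (((at - 5) * at + 8) * at - 4) * a;
  return 0.0;
}

// Bicubic resize with half-pixel sample centers and clamp-to-edge borders.
// [[Rcpp::export]]
NumericVector cpp_resize_bicubic(NumericVector img, int H, int W, int C,
                                 int Ho, int Wo) {
  NumericVector out((std::size_t)Ho * Wo * C);
  const double *pi = img.begin();
  double *po = out.begin();
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> ry(4 * Ho);
  std::vector<double> wy(4 * Ho);
  for (int r = 0; r < Ho; ++r) {
    const double src = (r + 0.5) * sh - 0.5;
    const int i0 = (int)std::floor(src) - 1;
    for (int t = 0; t < 4; ++t) {
      int ii = i0 + t;
      wy[4 * r + t] = cubic_w(src - ii);
      ry[4 * r + t] = std::min(std::max(ii, 0), H - 1);
    }
  }
  for (int c = 0; c < C; ++c) {
    const double *plane = pi + (std::size_t)c * H * W;
    double *oplane = po + (std::size_t)c * Ho * Wo;
    for (int q = 0; q < Wo; ++q) {
      const double src = (q + 0.5) * sw - 0.5;
      const int j0 = (int)std::floor(src) - 1;
      int cx[4]; double wx[4];
      for (int t = 0; t < 4; ++t) {
        int jj = j0 + t;
        wx[t] = cubic_w(src - jj);
        cx[t] = std::min(std::max(jj, 0), W - 1);
      }
      for (int r = 0; r < Ho; ++r) {
        double acc = 0.0;
        for (int ty = 0; ty < 4; ++ty) {
          const int rr = ry[4 * r + ty];
          double row = 0.0;
          for (int tx = 0; tx < 4; ++tx)
            row += wx[tx] * plane[rr + (std::size_t)H * cx[tx]];
          acc += wy[4 * r + ty] * row;
        }
        oplane[r + (std::size_t)Ho * q] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// Per-channel mean/variance over (H,W,B) of an [H,W,C,B] array.
// [[Rcpp::export]]
List cpp_chan_stats(NumericVector x, int hw, int C, int B) {
  NumericVector mu(C), va(C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double *chunk = px + ((std::size_t)b * C + c) * hw;
      for (int i = 0; i < hw; ++i) { s += chunk[i]; s2 += chunk[i] * chunk[i]; }
    }
    const double n = (double)hw * B;
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    va[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// Per-channel affine map y = x*a[c] + b[c] on an [H,W,C,B] array.
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, int hw, int C, int B,
                              NumericVector a, NumericVector bb) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = ((std::size_t)b * C + c) * hw;
      const double ac = a[c], bc = bb[c];
      for (int i = 0; i < hw; ++i) py[off + i] = px[off + i] * ac + bc;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Batch-norm backward (training mode) for an [H,W,C,B] array.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector gr, int hw, int C, int B,
               NumericVector gamma, NumericVector mu, NumericVector invstd,
               bool batch_stats, bool need_gx) {
  NumericVector ggamma(C), gbeta(C);
  NumericVector gx(need_gx ? x.size() : 0);
  const double *px = x.begin(), *pg = gr.begin();
  const double n = (double)hw * B;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int b = 0; b < B; ++b) {
      const std::size_t off = ((std::size_t)b * C + c) * hw;
      for (int i = 0; i < hw; ++i) {
        const double xh = (px[off + i] - mu[c]) * invstd[c];
        sg += pg[off + i];
        sgx += pg[off + i] * xh;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    if (need_gx) {
      double *pgx = gx.begin();
      const double k = gamma[c] * invstd[c];
      const double mg = batch_stats ? sg / n : 0.0;
      const double mgx = batch_stats ? sgx / n : 0.0;
      for (int b = 0; b < B; ++b) {
        const std::size_t off = ((std::size_t)b * C + c) * hw;
        for (int i = 0; i < hw; ++i) {
          const double xh = (px[off + i] - mu[c]) * invstd[c];
          pgx[off + i] = k * (pg[off + i] - mg - xh * mgx);
        }
      }
    }
  }
  if (need_gx) gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector y, NumericVector gr) {
  NumericVector gx(y.size());
  const double *py = y.begin(), *pg = gr.begin();
  double *px = gx.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) px[i] = py[i] > 0 ? pg[i] : 0;
  gx.attr("dim") = gr.attr("dim");
  return gx;
}

// Mean per-pixel softmax cross-entropy over an [H,W,C,B] logit array with
// integer labels [H,W,B] in 0..C-1. Channel stride is hw within a batch
// element (layout h,w,c,b).
// [[Rcpp::export]]
double cpp_ce_fw(NumericVector logits, int hw, int C, int B,
                 IntegerVector labels) {
  const double *pl = logits.begin();
  double acc = 0.0;
  for (int b = 0; b < B; ++b) {
    const double *base = pl + (std::size_t)b * C * hw;
    const int *lab = labels.begin() + (std::size_t)b * hw;
    for (int i = 0; i < hw; ++i) {
      double m = base[i];
      for (int c = 1; c < C; ++c) {
        const double v = base[i + (std::size_t)c * hw];
        if (v > m) m = v;
      }
      double z = 0.0;
      for (int c = 0; c < C; ++c) z += std::exp(base[i + (std::size_t)c * hw] - m);
      acc += base[i + (std::size_t)lab[i] * hw] - m - std::log(z);
    }
  }
  return -acc / ((double)hw * B);
}

// [[Rcpp::export]]
NumericVector cpp_ce_bw(NumericVector logits, int hw, int C, int B,
                        IntegerVector labels, double gscale) {
  NumericVector gx(logits.size());
  const double *pl = logits.begin();
  double *pg = gx.begin();
  const double k = gscale / ((double)hw * B);
  for (int b = 0; b < B; ++b) {
    const double *base = pl + (std::size_t)b * C * hw;
    double *gbase = pg + (std::size_t)b * C * hw;
    const int *lab = labels.begin() + (std::size_t)b * hw;
    for (int i = 0; i < hw; ++i) {
      double m = base[i];
      for (int c = 1; c < C; ++c) {
        const double v = base[i + (std::size_t)c * hw];
        if (v > m) m = v;
      }
      double z = 0.0;
      for (int c = 0; c < C; ++c) z += std::exp(base[i + (std::size_t)c * hw] - m);
      for (int c = 0; c < C; ++c)
        gbase[i + (std::size_t)c * hw] =
          k * (std::exp(base[i + (std::size_t)c * hw] - m) / z -
               (c == lab[i] ? 1.0 : 0.0));
    }
  }
  gx.attr("dim") = logits.attr("dim");
  return gx;
}
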