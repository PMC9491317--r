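// Low-level array kernels for the registration networks and spatial
// transforms. Arrays follow R column-major layout with dims (H, W, C) in 2D
// and (H, W, D, C) in 3D; displacement fields carry one channel per spatial
// axis, in voxel units.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2D convolution, stride 1, zero padding to "same" size, odd kernel.
// Kernel layout: dims (k, k, Cin, Cout).
// ---------------------------------------------------------------------------

static void im2col2d(const double* x, int H, int W, int Cin, int k,
                     double* M) {
  // M: (H*W) x (k*k*Cin), column (di + k*(dj + k*ci)); zero padding
  const int pad = (k - 1) / 2;
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  R_xlen_t col = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + HW * ci;
    for (int dj = 0; dj < k; ++dj) {
      const int oj = dj - pad;
      for (int di = 0; di < k; ++di) {
        const int oi = di - pad;
        double* Mc = M + HW * (col++);
        for (int j = 0; j < W; ++j) {
          const int jj = j + oj;
          double* Mcol = Mc + static_cast<R_xlen_t>(H) * j;
          if (jj < 0 || jj >= W) {
            std::fill(Mcol, Mcol + H, 0.0);
            continue;
          }
          const double* xcol = xc + static_cast<R_xlen_t>(H) * jj;
          const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
          for (int i = 0; i < i0; ++i) Mcol[i] = 0.0;
          for (int i = i0; i <= i1; ++i) Mcol[i] = xcol[i + oi];
          for (int i = i1 + 1; i < H; ++i) Mcol[i] = 0.0;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(const NumericVector& x, int H, int W, int Cin,
                        const NumericVector& w, const NumericVector& b,
                        int Cout, int k) {
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  const int K = k * k * Cin;
  NumericVector y(HW * Cout);
  std::vector<double> M(HW * K);
  im2col2d(x.begin(), H, W, Cin, k, M.data());
  for (int co = 0; co < Cout; ++co)
    std::fill(y.begin() + HW * co, y.begin() + HW * (co + 1), b[co]);
  const int m = static_cast<int>(HW);
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &m, &Cout, &K, &one, M.data(), &m,
                  const_cast<double*>(w.begin()), &K, &one, y.begin(), &m
                  FCONE FCONE);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(const NumericVector& x, int H, int W, int Cin,
               const NumericVector& w, int Cout, int k,
               const NumericVector& gy) {
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  const int K = k * k * Cin;
  const int pad = (k - 1) / 2;
  NumericVector gx(HW * Cin);
  NumericVector gw(static_cast<R_xlen_t>(K) * Cout);
  NumericVector gb(Cout);
  std::vector<double> M(HW * K);
  im2col2d(x.begin(), H, W, Cin, k, M.data());
  const int m = static_cast<int>(HW);
  const double one = 1.0, zero = 0.0;
  // gw = M^T * gy
  F77_CALL(dgemm)("T", "N", &K, &Cout, &m, &one, M.data(), &m,
                  const_cast<double*>(gy.begin()), &m, &zero, gw.begin(), &K
                  FCONE FCONE);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    const double* gc = gy.begin() + HW * co;
    for (R_xlen_t t = 0; t < HW; ++t) acc += gc[t];
    gb[co] = acc;
  }
  // gM = gy * w^T, then col2im accumulate into gx
  std::vector<double> gM(HW * K);
  F77_CALL(dgemm)("N", "T", &m, &K, &Cout, &one,
                  const_cast<double*>(gy.begin()), &m,
                  const_cast<double*>(w.begin()), &K, &zero, gM.data(), &m
                  FCONE FCONE);
  R_xlen_t col = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gx.begin() + HW * ci;
    for (int dj = 0; dj < k; ++dj) {
      const int oj = dj - pad;
      for (int di = 0; di < k; ++di) {
        const int oi = di - pad;
        const double* Mc = gM.data() + HW * (col++);
        const int j0 = std::max(0, -oj), j1 = std::min(W - 1, W - 1 - oj);
        const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
        for (int j = j0; j <= j1; ++j) {
          const double* Mcol = Mc + static_cast<R_xlen_t>(H) * j;
          double* gxcol = gxc + static_cast<R_xlen_t>(H) * (j + oj);
          for (int i = i0; i <= i1; ++i) gxcol[i + oi] += Mcol[i];
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x max pooling / nearest-neighbour upsampling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List maxpool2_fw(const NumericVector& x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + static_cast<R_xlen_t>(H) * W * c;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -INFINITY;
        int bestix = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const R_xlen_t ix = ii + static_cast<R_xlen_t>(H) * jj;
            if (xc[ix] > best) { best = xc[ix]; bestix = static_cast<int>(ix); }
          }
        }
        const R_xlen_t o = i + static_cast<R_xlen_t>(Ho) * (j + static_cast<R_xlen_t>(Wo) * c);
        y[o] = best;
        idx[o] = bestix;  // within-channel flat index
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(const IntegerVector& idx, const NumericVector& gy,
                          int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + static_cast<R_xlen_t>(H) * W * c;
    const R_xlen_t off = static_cast<R_xlen_t>(Ho) * Wo * c;
    for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(Ho) * Wo; ++t)
      gxc[idx[off + t]] += gy[off + t];
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fw(const NumericVector& x, int H, int W, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<R_xlen_t>(H) * W * c;
    double* yc = y.begin() + static_cast<R_xlen_t>(Ho) * Wo * c;
    for (int j = 0; j < Wo; ++j) {
      const double* xcol = xc + static_cast<R_xlen_t>(H) * (j / 2);
      double* ycol = yc + static_cast<R_xlen_t>(Ho) * j;
      for (int i = 0; i < Ho; ++i) ycol[i] = xcol[i / 2];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(const NumericVector& gy, int H, int W, int C) {
  // H, W are the *input* (coarse) dims
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + static_cast<R_xlen_t>(H) * W * c;
    const double* gyc = gy.begin() + static_cast<R_xlen_t>(Ho) * Wo * c;
    for (int j = 0; j < Wo; ++j) {
      const double* gcol = gyc + static_cast<R_xlen_t>(Ho) * j;
      double* gxcol = gxc + static_cast<R_xlen_t>(H) * (j / 2);
      for (int i = 0; i < Ho; ++i) gxcol[i / 2] += gcol[i];
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Differentiable grid sampling (pull-back warp), edge-clamped.
// disp has 2 (or 3) channels: displacement along each axis in voxels.
// out(p) = img(p + disp(p)), sampled with linear (bilinear/trilinear)
// interpolation; sampling positions outside the grid are clamped to the edge.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sample2_linear_fw(const NumericVector& img, int H, int W, int C,
                                const NumericVector& disp) {
  NumericVector out(static_cast<R_xlen_t>(H) * W * C);
  const double* d1 = disp.begin();
  const double* d2 = disp.begin() + static_cast<R_xlen_t>(H) * W;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const R_xlen_t t = i + static_cast<R_xlen_t>(H) * j;
      double pi = i + d1[t], pj = j + d2[t];
      if (!(pi >= 0)) pi = 0; if (pi > H - 1) pi = H - 1;
      if (!(pj >= 0)) pj = 0; if (pj > W - 1) pj = W - 1;
      const int i0 = std::min(static_cast<int>(std::floor(pi)), H - 2 < 0 ? 0 : H - 2);
      const int j0 = std::min(static_cast<int>(std::floor(pj)), W - 2 < 0 ? 0 : W - 2);
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      const double fi = pi - i0, fj = pj - j0;
      for (int c = 0; c < C; ++c) {
        const double* im = img.begin() + static_cast<R_xlen_t>(H) * W * c;
        const double v00 = im[i0 + static_cast<R_xlen_t>(H) * j0];
        const double v10 = im[i1 + static_cast<R_xlen_t>(H) * j0];
        const double v01 = im[i0 + static_cast<R_xlen_t>(H) * j1];
        const double v11 = im[i1 + static_cast<R_xlen_t>(H) * j1];
        out[t + static_cast<R_xlen_t>(H) * W * c] =
          (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
          (1 - fi) * fj * v01 + fi * fj * v11;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List sample2_linear_bw(const NumericVector& img, int H, int W, int C,
                       const NumericVector& disp, const NumericVector& gy) {
  NumericVector gimg(static_cast<R_xlen_t>(H) * W * C);
  NumericVector gdisp(static_cast<R_xlen_t>(H) * W * 2);
  const double* d1 = disp.begin();
  const double* d2 = disp.begin() + static_cast<R_xlen_t>(H) * W;
  double* g1 = gdisp.begin();
  double* g2 = gdisp.begin() + static_cast<R_xlen_t>(H) * W;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const R_xlen_t t = i + static_cast<R_xlen_t>(H) * j;
      double pi = i + d1[t], pj = j + d2[t];
      const bool ci_ = (pi < 0 || pi > H - 1);  // clamped => zero coord grad
      const bool cj_ = (pj < 0 || pj > W - 1);
      if (!(pi >= 0)) pi = 0; if (pi > H - 1) pi = H - 1;
      if (!(pj >= 0)) pj = 0; if (pj > W - 1) pj = W - 1;
      const int i0 = std::min(static_cast<int>(std::floor(pi)), H - 2 < 0 ? 0 : H - 2);
      const int j0 = std::min(static_cast<int>(std::floor(pj)), W - 2 < 0 ? 0 : W - 2);
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      const double fi = pi - i0, fj = pj - j0;
      double gpi = 0.0, gpj = 0.0;
      for (int c = 0; c < C; ++c) {
        const double* im = img.begin() + static_cast<R_xlen_t>(H) * W * c;
        double* gm = gimg.begin() + static_cast<R_xlen_t>(H) * W * c;
        const double g = gy[t + static_cast<R_xlen_t>(H) * W * c];
        const R_xlen_t a00 = i0 + static_cast<R_xlen_t>(H) * j0;
        const R_xlen_t a10 = i1 + static_cast<R_xlen_t>(H) * j0;
        const R_xlen_t a01 = i0 + static_cast<R_xlen_t>(H) * j1;
        const R_xlen_t a11 = i1 + static_cast<R_xlen_t>(H) * j1;
        gm[a00] += g * (1 - fi) * (1 - fj);
        gm[a10] += g * fi * (1 - fj);
        gm[a01] += g * (1 - fi) * fj;
        gm[a11] += g * fi * fj;
        gpi += g * ((im[a10] - im[a00]) * (1 - fj) + (im[a11] - im[a01]) * fj);
        gpj += g * ((im[a01] - im[a00]) * (1 - fi) + (im[a11] - im[a10]) * fi);
      }
      g1[t] = ci_ ? 0.0 : gpi;
      g2[t] = cj_ ? 0.0 : gpj;
    }
  }
  return List::create(_["gimg"] = gimg, _["gdisp"] = gdisp);
}

// [[Rcpp::export]]
NumericVector sample2_nearest_fw(const NumericVector& img, int H, int W, int C,
                                 const NumericVector& disp) {
  NumericVector out(static_cast<R_xlen_t>(H) * W * C);
  const double* d1 = disp.begin();
  const double* d2 = disp.begin() + static_cast<R_xlen_t>(H) * W;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const R_xlen_t t = i + static_cast<R_xlen_t>(H) * j;
      const double pi = i + d1[t], pj = j + d2[t];
      int ii = std::isfinite(pi) ? static_cast<int>(std::lround(pi)) : 0;
      int jj = std::isfinite(pj) ? static_cast<int>(std::lround(pj)) : 0;
      if (ii < 0) ii = 0; if (ii > H - 1) ii = H - 1;
      if (jj < 0) jj = 0; if (jj > W - 1) jj = W - 1;
      for (int c = 0; c < C; ++c)
        out[t + static_cast<R_xlen_t>(H) * W * c] =
          img[ii + static_cast<R_xlen_t>(H) * (jj + static_cast<R_xlen_t>(W) * c)];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D linear / nearest sampling (transforms support; networks train in 2D)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sample3_linear_fw(const NumericVector& img, int H, int W, int D,
                                int C, const NumericVector& disp) {
  const R_xlen_t N = static_cast<R_xlen_t>(H) * W * D;
  NumericVector out(N * C);
  const double* d1 = disp.begin();
  const double* d2 = disp.begin() + N;
  const double* d3 = disp.begin() + 2 * N;
  for (int kz = 0; kz < D; ++kz) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const R_xlen_t t = i + static_cast<R_xlen_t>(H) * (j + static_cast<R_xlen_t>(W) * kz);
        double pi = i + d1[t], pj = j + d2[t], pk = kz + d3[t];
        if (!(pi >= 0)) pi = 0; if (pi > H - 1) pi = H - 1;
        if (!(pj >= 0)) pj = 0; if (pj > W - 1) pj = W - 1;
        if (!(pk >= 0)) pk = 0; if (pk > D - 1) pk = D - 1;
        const int i0 = std::min(static_cast<int>(std::floor(pi)), std::max(0, H - 2));
        const int j0 = std::min(static_cast<int>(std::floor(pj)), std::max(0, W - 2));
        const int k0 = std::min(static_cast<int>(std::floor(pk)), std::max(0, D - 2));
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1),
                  k1 = std::min(k0 + 1, D - 1);
        const double fi = pi - i0, fj = pj - j0, fk = pk - k0;
        for (int c = 0; c < C; ++c) {
          const double* im = img.begin() + N * c;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int zz = dz ? k1 : k0;
            const double wz = dz ? fk : 1 - fk;
            for (int dy = 0; dy < 2; ++dy) {
              const int yy = dy ? j1 : j0;
              const double wy = dy ? fj : 1 - fj;
              for (int dx = 0; dx < 2; ++dx) {
                const int xx = dx ? i1 : i0;
                const double wx = dx ? fi : 1 - fi;
                acc += wx * wy * wz *
                  im[xx + static_cast<R_xlen_t>(H) * (yy + static_cast<R_xlen_t>(W) * zz)];
              }
            }
          }
          out[t + N * c] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sample3_nearest_fw(const NumericVector& img, int H, int W, int D,
                                 int C, const NumericVector& disp) {
  const R_xlen_t N = static_cast<R_xlen_t>(H) * W * D;
  NumericVector out(N * C);
  const double* d1 = disp.begin();
  const double* d2 = disp.begin() + N;
  const double* d3 = disp.begin() + 2 * N;
  for (int kz = 0; kz < D; ++kz) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const R_xlen_t t = i + static_cast<R_xlen_t>(H) * (j + static_cast<R_xlen_t>(W) * kz);
        const double pi = i + d1[t], pj = j + d2[t], pk = kz + d3[t];
        int ii = std::isfinite(pi) ? static_cast<int>(std::lround(pi)) : 0;
        int jj = std::isfinite(pj) ? static_cast<int>(std::lround(pj)) : 0;
        int kk = std::isfinite(pk) ? static_cast<int>(std::lround(pk)) : 0;
        if (ii < 0) ii = 0; if (ii > H - 1) ii = H - 1;
        if (jj < 0) jj = 0; if (jj > W - 1) jj = W - 1;
        if (kk < 0) kk = 0; if (kk > D - 1) kk = D - 1;
        for (int c = 0; c < C; ++c)
          out[t + N * c] =
            img[ii + static_cast<R_xlen_t>(H) * (jj + static_cast<R_xlen_t>(W) * (kk + static_cast<R_xlen_t>(D) * c))];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Box filter (sum over a w x w window, edge-truncated) used by local NCC.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector boxsum2(const NumericVector& x, int H, int W, int w) {
  const int r = (w - 1) / 2;
  NumericVector tmp(static_cast<R_xlen_t>(H) * W), out(static_cast<R_xlen_t>(H) * W);
  // sum along axis 1
  for (int j = 0; j < W; ++j) {
    const double* xc = x.begin() + static_cast<R_xlen_t>(H) * j;
    double* tc = tmp.begin() + static_cast<R_xlen_t>(H) * j;
    double run = 0.0;
    for (int i = 0; i <= std::min(r, H - 1); ++i) run += xc[i];
    for (int i = 0; i < H; ++i) {
      tc[i] = run;
      const int add = i + r + 1, rem = i - r;
      if (add < H) run += xc[add];
      if (rem >= 0) run -= xc[rem];
    }
  }
  // sum along axis 2
  for (int i = 0; i < H; ++i) {
    double run = 0.0;
    for (int j = 0; j <= std::min(r, W - 1); ++j) run += tmp[i + static_cast<R_xlen_t>(H) * j];
    for (int j = 0; j < W; ++j) {
      out[i + static_cast<R_xlen_t>(H) * j] = run;
      const int add = j + r + 1, rem = j - r;
      if (add < W) run += tmp[i + static_cast<R_xlen_t>(H) * add];
      if (rem >= 0) run -= tmp[i + static_cast<R_xlen_t>(H) * rem];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused helpers for the training loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector lrelu_fwc(const NumericVector& x, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_bwc(const NumericVector& y, const NumericVector& g,
                        double slope) {
  NumericVector gx(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i)
    gx[i] = y[i] > 0 ? g[i] : slope * g[i];
  return gx;
}

// In-place Adam update; theta, m and v are modified by reference (callers
// must own unshared copies).
// [[Rcpp::export]]
void adam_inplace(NumericVector theta, NumericVector m, NumericVector v,
                  const NumericVector& g, double lr, int t,
                  double beta1 = 0.9, double beta2 = 0.999,
                  double eps = 1e-8) {
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    m[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    theta[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
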