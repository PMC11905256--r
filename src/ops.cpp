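// Compiled kernels for the 3D segmentation network.
// Tensor layout throughout: numeric array with dim (C, D, H, W, B),
// channel fastest-varying, so each voxel's channel vector is contiguous.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Valid output range [o0, o1) for kernel offset shift sz:
// i = o*stride + sz must lie in [0, n).
static inline void valid_range(int n, int on, int stride, int sz,
                               int& o0, int& o1) {
  o0 = 0;
  while (o0 < on && o0 * stride + sz < 0) ++o0;
  o1 = on;
  while (o1 > o0 && (o1 - 1) * stride + sz >= n) --o1;
}

// col matrix: (C*k^3) x (oD*oH*oW); kernel offset t = kz + k*(ky + k*kx),
// rows [t*C, t*C+C) hold the C input channels at that offset. Only valid
// entries are written; the caller provides a zero-initialized col whose
// out-of-range entries stay zero (identical across samples).
static void im2col(const double* x, int C, int D, int H, int W,
                   int k, int stride, int dil, int pad,
                   int oD, int oH, int oW, arma::mat& col) {
  const size_t colstride = (size_t)C * k * k * k;
  for (int kx = 0; kx < k; ++kx) {
    int sx = kx * dil - pad, ox0, ox1;
    valid_range(W, oW, stride, sx, ox0, ox1);
    for (int ky = 0; ky < k; ++ky) {
      int sy = ky * dil - pad, oy0, oy1;
      valid_range(H, oH, stride, sy, oy0, oy1);
      for (int kz = 0; kz < k; ++kz) {
        int sz = kz * dil - pad, oz0, oz1;
        valid_range(D, oD, stride, sz, oz0, oz1);
        size_t t = (size_t)C * (kz + k * (ky + k * kx));
        for (int ox = ox0; ox < ox1; ++ox) {
          int ix = ox * stride + sx;
          for (int oy = oy0; oy < oy1; ++oy) {
            int iy = oy * stride + sy;
            double* dst = col.memptr() +
              colstride * (oz0 + (size_t)oD * (oy + (size_t)oH * ox)) + t;
            const double* src = x + (size_t)C *
              ((oz0 * stride + sz) + (size_t)D * (iy + (size_t)H * ix));
            if (stride == 1) {
              for (int oz = oz0; oz < oz1; ++oz) {
                std::copy(src, src + C, dst);
                src += C; dst += colstride;
              }
            } else {
              for (int oz = oz0; oz < oz1; ++oz) {
                std::copy(src, src + C, dst);
                src += (size_t)C * stride; dst += colstride;
              }
            }
          }
        }
      }
    }
  }
}

// Accumulate dcol back into dx (the adjoint of im2col); invalid (padding)
// entries of dcol are skipped.
static void col2im(const arma::mat& col, double* x, int C, int D, int H,
                   int W, int k, int stride, int dil, int pad,
                   int oD, int oH, int oW) {
  const size_t colstride = (size_t)C * k * k * k;
  for (int kx = 0; kx < k; ++kx) {
    int sx = kx * dil - pad, ox0, ox1;
    valid_range(W, oW, stride, sx, ox0, ox1);
    for (int ky = 0; ky < k; ++ky) {
      int sy = ky * dil - pad, oy0, oy1;
      valid_range(H, oH, stride, sy, oy0, oy1);
      for (int kz = 0; kz < k; ++kz) {
        int sz = kz * dil - pad, oz0, oz1;
        valid_range(D, oD, stride, sz, oz0, oz1);
        size_t t = (size_t)C * (kz + k * (ky + k * kx));
        for (int ox = ox0; ox < ox1; ++ox) {
          int ix = ox * stride + sx;
          for (int oy = oy0; oy < oy1; ++oy) {
            int iy = oy * stride + sy;
            const double* src = col.memptr() +
              colstride * (oz0 + (size_t)oD * (oy + (size_t)oH * ox)) + t;
            double* dst = x + (size_t)C *
              ((oz0 * stride + sz) + (size_t)D * (iy + (size_t)H * ix));
            for (int oz = oz0; oz < oz1; ++oz) {
              for (int c = 0; c < C; ++c) dst[c] += src[c];
              src += colstride; dst += (size_t)C * stride;
            }
          }
        }
      }
    }
  }
}


// Float variant: casts to single precision while filling, halving the
// memory traffic of the GEMM working set. Network math runs in float
// internally; tensors at the R surface remain double.
static void fim2col(const double* x, int C, int D, int H, int W,
                    int k, int stride, int dil, int pad,
                    int oD, int oH, int oW, arma::fmat& col) {
  const size_t colstride = (size_t)C * k * k * k;
  for (int kx = 0; kx < k; ++kx) {
    int sx = kx * dil - pad, ox0, ox1;
    valid_range(W, oW, stride, sx, ox0, ox1);
    for (int ky = 0; ky < k; ++ky) {
      int sy = ky * dil - pad, oy0, oy1;
      valid_range(H, oH, stride, sy, oy0, oy1);
      for (int kz = 0; kz < k; ++kz) {
        int sz = kz * dil - pad, oz0, oz1;
        valid_range(D, oD, stride, sz, oz0, oz1);
        size_t t = (size_t)C * (kz + k * (ky + k * kx));
        for (int ox = ox0; ox < ox1; ++ox) {
          int ix = ox * stride + sx;
          for (int oy = oy0; oy < oy1; ++oy) {
            int iy = oy * stride + sy;
            float* dst = col.memptr() +
              colstride * (oz0 + (size_t)oD * (oy + (size_t)oH * ox)) + t;
            const double* src = x + (size_t)C *
              ((oz0 * stride + sz) + (size_t)D * (iy + (size_t)H * ix));
            for (int oz = oz0; oz < oz1; ++oz) {
              for (int c = 0; c < C; ++c) dst[c] = (float)src[c];
              src += (size_t)C * stride; dst += colstride;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, arma::mat w, arma::vec b,
                             int k, int stride, int dil) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3], B = xd[4];
  int pad = dil * (k - 1) / 2;
  int oD = out_dim(D, k, stride, pad, dil);
  int oH = out_dim(H, k, stride, pad, dil);
  int oW = out_dim(W, k, stride, pad, dil);
  int Cout = w.n_rows;
  size_t nvox = (size_t)oD * oH * oW;
  NumericVector y(Rcpp::no_init((R_xlen_t)((size_t)Cout * nvox * B)));
  y.attr("dim") = IntegerVector::create(Cout, oD, oH, oW, B);
  if (k == 1 && stride == 1) {
    // pointwise convolution: one GEMM over the whole batch
    const arma::mat xs(const_cast<double*>(REAL(x)), C, nvox * B, false, true);
    arma::mat ys(REAL(y), Cout, nvox * B, false, true);
    ys = w * xs;
    ys.each_col() += b;
    return y;
  }
  arma::fmat col((size_t)C * k * k * k, nvox, arma::fill::zeros);
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
  arma::fmat fys(Cout, nvox);
  for (int s = 0; s < B; ++s) {
    fim2col(REAL(x) + (size_t)C * D * H * W * s, C, D, H, W,
            k, stride, dil, pad, oD, oH, oW, col);
    fys = wf * col;
    fys.each_col() += bf;
    double* yp = REAL(y) + (size_t)Cout * nvox * s;
    const float* fp = fys.memptr();
    for (size_t i = 0; i < (size_t)Cout * nvox; ++i) yp[i] = fp[i];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, arma::mat w, NumericVector dy,
                    int k, int stride, int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3], B = xd[4];
  IntegerVector yd = dy.attr("dim");
  int Cout = yd[0], oD = yd[1], oH = yd[2], oW = yd[3];
  int pad = dil * (k - 1) / 2;
  size_t nvox = (size_t)oD * oH * oW;
  NumericVector dx;
  if (k == 1 && stride == 1) {
    const arma::mat xs(const_cast<double*>(REAL(x)), C, nvox * B, false, true);
    const arma::mat dys(const_cast<double*>(REAL(dy)), Cout, nvox * B,
                        false, true);
    arma::mat dw = dys * xs.t();
    arma::vec db = arma::sum(dys, 1);
    if (need_dx) {
      dx = NumericVector(Rcpp::no_init((R_xlen_t)((size_t)C * D * H * W * B)));
      dx.attr("dim") = xd;
      arma::mat dxs(REAL(dx), C, nvox * B, false, true);
      dxs = w.t() * dys;
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }
  const int K3 = k * k * k;
  arma::vec db(Cout, arma::fill::zeros);
  if (stride == 1) {
    // dw accumulated transposed (tall-skinny GEMM); dx computed directly as
    // a correlation of dy with the spatially flipped, transposed kernel, so
    // no col2im scatter is needed and writes are contiguous.
    arma::fmat dwt((size_t)C * K3, Cout, arma::fill::zeros);
    arma::fmat colx((size_t)C * K3, nvox, arma::fill::zeros);
    arma::fmat coly, w2;
    arma::fmat fdx(need_dx ? C : 0, need_dx ? nvox : 0);
    if (need_dx) {
      dx = NumericVector(Rcpp::no_init((R_xlen_t)((size_t)C * D * H * W * B)));
      dx.attr("dim") = xd;
      coly.zeros((size_t)Cout * K3, nvox);
      w2.set_size(C, (size_t)Cout * K3);
      for (int kx = 0; kx < k; ++kx)
        for (int ky = 0; ky < k; ++ky)
          for (int kz = 0; kz < k; ++kz) {
            int t = kz + k * (ky + k * kx);
            int tf = (k - 1 - kz) + k * ((k - 1 - ky) + k * (k - 1 - kx));
            for (int co = 0; co < Cout; ++co)
              for (int c = 0; c < C; ++c)
                w2(c, co + (size_t)Cout * tf) =
                  (float)w(co, c + (size_t)C * t);
          }
    }
    arma::fmat fdys(Cout, nvox);
    for (int s = 0; s < B; ++s) {
      const double* dyp = REAL(dy) + (size_t)Cout * nvox * s;
      float* fp = fdys.memptr();
      for (size_t i = 0; i < (size_t)Cout * nvox; ++i) fp[i] = (float)dyp[i];
      fim2col(REAL(x) + (size_t)C * D * H * W * s, C, D, H, W,
              k, stride, dil, pad, oD, oH, oW, colx);
      const arma::mat dys(const_cast<double*>(REAL(dy)) +
                          (size_t)Cout * nvox * s, Cout, nvox, false, true);
      dwt += colx * fdys.t();
      db += arma::sum(dys, 1);
      if (need_dx) {
        fim2col(REAL(dy) + (size_t)Cout * nvox * s, Cout, oD, oH, oW,
                k, stride, dil, pad, oD, oH, oW, coly);
        fdx = w2 * coly;
        double* dxp = REAL(dx) + (size_t)C * D * H * W * s;
        const float* xp = fdx.memptr();
        for (size_t i = 0; i < (size_t)C * nvox; ++i) dxp[i] = xp[i];
      }
    }
    arma::mat dwd = arma::conv_to<arma::mat>::from(dwt.t());
    return List::create(_["dx"] = dx, _["dw"] = dwd, _["db"] = db);
  }
  arma::mat dw(Cout, (size_t)C * K3, arma::fill::zeros);
  if (need_dx) {
    dx = NumericVector((size_t)C * D * H * W * B);   // zero-initialized
    dx.attr("dim") = xd;
  }
  arma::mat col((size_t)C * K3, nvox, arma::fill::zeros);
  arma::mat wt = w.t();
  arma::mat dcol((size_t)C * K3, nvox);
  for (int s = 0; s < B; ++s) {
    im2col(REAL(x) + (size_t)C * D * H * W * s, C, D, H, W,
           k, stride, dil, pad, oD, oH, oW, col);
    const arma::mat dys(const_cast<double*>(REAL(dy)) +
                        (size_t)Cout * nvox * s, Cout, nvox, false, true);
    dw += dys * col.t();
    db += arma::sum(dys, 1);
    if (need_dx) {
      dcol = wt * dys;
      col2im(dcol, REAL(dx) + (size_t)C * D * H * W * s,
             C, D, H, W, k, stride, dil, pad, oD, oH, oW);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Per-axis interpolation index/weight tables for factor-2 trilinear
// upsampling with half-voxel center alignment.
static void up2_axis(int n, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w0, std::vector<double>& w1) {
  int on = 2 * n;
  i0.resize(on); i1.resize(on); w0.resize(on); w1.resize(on);
  for (int o = 0; o < on; ++o) {
    double z = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(z);
    double f = z - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    i0[o] = lo; i1[o] = hi; w0[o] = 1.0 - f; w1[o] = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3], B = xd[4];
  int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector y((size_t)C * oD * oH * oW * B);
  y.attr("dim") = IntegerVector::create(C, oD, oH, oW, B);
  std::vector<int> zi0, zi1, yi0, yi1, xi0, xi1;
  std::vector<double> zw0, zw1, yw0, yw1, xw0, xw1;
  up2_axis(D, zi0, zi1, zw0, zw1);
  up2_axis(H, yi0, yi1, yw0, yw1);
  up2_axis(W, xi0, xi1, xw0, xw1);
  for (int s = 0; s < B; ++s) {
    const double* xs = REAL(x) + (size_t)C * D * H * W * s;
    double* ys = REAL(y) + (size_t)C * oD * oH * oW * s;
    for (int ox = 0; ox < oW; ++ox)
      for (int oy = 0; oy < oH; ++oy)
        for (int oz = 0; oz < oD; ++oz) {
          double* yp = ys + (size_t)C * (oz + (size_t)oD * (oy + (size_t)oH * ox));
          int izs[2] = {zi0[oz], zi1[oz]}; double wzs[2] = {zw0[oz], zw1[oz]};
          int iys[2] = {yi0[oy], yi1[oy]}; double wys[2] = {yw0[oy], yw1[oy]};
          int ixs[2] = {xi0[ox], xi1[ox]}; double wxs[2] = {xw0[ox], xw1[ox]};
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                double wgt = wzs[a] * wys[bb] * wxs[cc];
                if (wgt == 0.0) continue;
                const double* xp = xs + (size_t)C * (izs[a] + (size_t)D * (iys[bb] + (size_t)H * ixs[cc]));
                for (int c = 0; c < C; ++c) yp[c] += wgt * xp[c];
              }
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector in_dim) {
  int C = in_dim[0], D = in_dim[1], H = in_dim[2], W = in_dim[3], B = in_dim[4];
  int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector dx((size_t)C * D * H * W * B);
  dx.attr("dim") = in_dim;
  std::vector<int> zi0, zi1, yi0, yi1, xi0, xi1;
  std::vector<double> zw0, zw1, yw0, yw1, xw0, xw1;
  up2_axis(D, zi0, zi1, zw0, zw1);
  up2_axis(H, yi0, yi1, yw0, yw1);
  up2_axis(W, xi0, xi1, xw0, xw1);
  for (int s = 0; s < B; ++s) {
    double* dxs = REAL(dx) + (size_t)C * D * H * W * s;
    const double* dys = REAL(dy) + (size_t)C * oD * oH * oW * s;
    for (int ox = 0; ox < oW; ++ox)
      for (int oy = 0; oy < oH; ++oy)
        for (int oz = 0; oz < oD; ++oz) {
          const double* dp = dys + (size_t)C * (oz + (size_t)oD * (oy + (size_t)oH * ox));
          int izs[2] = {zi0[oz], zi1[oz]}; double wzs[2] = {zw0[oz], zw1[oz]};
          int iys[2] = {yi0[oy], yi1[oy]}; double wys[2] = {yw0[oy], yw1[oy]};
          int ixs[2] = {xi0[ox], xi1[ox]}; double wxs[2] = {xw0[ox], xw1[ox]};
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                double wgt = wzs[a] * wys[bb] * wxs[cc];
                if (wgt == 0.0) continue;
                double* xp = dxs + (size_t)C * (izs[a] + (size_t)D * (iys[bb] + (size_t)H * ixs[cc]));
                for (int c = 0; c < C; ++c) xp[c] += wgt * dp[c];
              }
        }
  }
  return dx;
}

// Minimum Euclidean distance from each row of A to the rows of B.
// Used by the average symmetric surface distance on physical coordinates.
// [[Rcpp::export]]
arma::vec cpp_min_dists(const arma::mat& A, const arma::mat& B) {
  arma::vec out(A.n_rows);
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      double s = 0.0;
      for (arma::uword c = 0; c < A.n_cols; ++c) {
        double d = A(i, c) - B(j, c);
        s += d * d;
      }
      if (s < best) best = s;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
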