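#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Kernels for 3x3x3 convolution via im2col + BLAS matmul (done in R).
// Arrays are column-major with dims (X, Y, Z, C); padding is fixed at 1
// voxel so stride-1 convolutions preserve the spatial grid. The stride-1
// path copies whole contiguous rows (memcpy) with the boundary handled
// separately, which keeps the transform memory-bandwidth bound.

static inline int out_extent(int n, int s) { return (n - 1) / s + 1; }

// [[Rcpp::export(name = ".cpp_im2col3")]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, IntegerVector stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int ox = out_extent(X, sx), oy = out_extent(Y, sy), oz = out_extent(Z, sz);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericMatrix col(no_init((int)nout, 27 * C));
  const double *px = x.begin();
  double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * X * Y * Z;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int kidx = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
          double *dst = pc + (R_xlen_t)kidx * nout;
          for (int iz = 0; iz < oz; ++iz) {
            const int zz = iz * sz + kz;
            for (int iy = 0; iy < oy; ++iy) {
              const int yy = iy * sy + ky;
              double *drow = dst + ((R_xlen_t)iz * oy + iy) * ox;
              if (zz < 0 || zz >= Z || yy < 0 || yy >= Y) {
                std::memset(drow, 0, sizeof(double) * ox);
                continue;
              }
              const double *src = xc + ((R_xlen_t)zz * Y + yy) * X;
              if (sx == 1) {
                // valid input x-range for this kernel offset
                const int lo = (kx < 0) ? 1 : 0;          // ix >= -kx
                const int hi = (kx > 0) ? ox - 1 : ox;    // ix < X - kx
                if (lo) drow[0] = 0.0;
                if (hi < ox) drow[ox - 1] = 0.0;
                std::memcpy(drow + lo, src + lo + kx, sizeof(double) * (hi - lo));
              } else {
                for (int ix = 0; ix < ox; ++ix) {
                  const int xx = ix * sx + kx;
                  drow[ix] = (xx < 0 || xx >= X) ? 0.0 : src[xx];
                }
              }
            }
          }
        }
  }
  return col;
}

// Scatter-add of a column matrix (n_out x 27C) back onto the input grid:
// adjoint of cpp_im2col3, used for the gradient w.r.t. the convolution input.
// [[Rcpp::export(name = ".cpp_col2im3")]]
NumericVector cpp_col2im3(NumericMatrix col, IntegerVector dims, IntegerVector stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int ox = out_extent(X, sx), oy = out_extent(Y, sy), oz = out_extent(Z, sz);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector x((R_xlen_t)X * Y * Z * C);   // zero-initialized on purpose
  double *px = x.begin();
  const double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = px + (R_xlen_t)c * X * Y * Z;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int kidx = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
          const double *src = pc + (R_xlen_t)kidx * nout;
          for (int iz = 0; iz < oz; ++iz) {
            const int zz = iz * sz + kz;
            if (zz < 0 || zz >= Z) continue;
            for (int iy = 0; iy < oy; ++iy) {
              const int yy = iy * sy + ky;
              if (yy < 0 || yy >= Y) continue;
              const double *srow = src + ((R_xlen_t)iz * oy + iy) * ox;
              double *drow = xc + ((R_xlen_t)zz * Y + yy) * X;
              if (sx == 1) {
                const int lo = (kx < 0) ? 1 : 0;
                const int hi = (kx > 0) ? ox - 1 : ox;
                double *d = drow + lo + kx;
                const double *s = srow + lo;
                const int n = hi - lo;
                for (int i = 0; i < n; ++i) d[i] += s[i];
              } else {
                for (int ix = 0; ix < ox; ++ix) {
                  const int xx = ix * sx + kx;
                  if (xx >= 0 && xx < X) drow[xx] += srow[ix];
                }
              }
            }
          }
        }
  }
  x.attr("dim") = dims;
  return x;
}


// ---- fused convolution forward/backward ----------------------------------
//
// The im2col matrix for a full-resolution level is hundreds of MB and is
// rebuilt every iteration; materializing it as an R object would churn the
// allocator. Instead it lives in a persistent C++ scratch buffer and the
// matrix products go straight through BLAS dgemm.

#include <R_ext/BLAS.h>
#include <vector>

#ifndef FCONE
# define FCONE
#endif

static std::vector<double> g_col_buf;
static std::vector<double> g_aux_buf;

static void im2col_into(double *pc, const double *px,
                        const int *dims, const int *stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int ox = out_extent(X, sx), oy = out_extent(Y, sy), oz = out_extent(Z, sz);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * X * Y * Z;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int kidx = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
          double *dst = pc + (R_xlen_t)kidx * nout;
          for (int iz = 0; iz < oz; ++iz) {
            const int zz = iz * sz + kz;
            for (int iy = 0; iy < oy; ++iy) {
              const int yy = iy * sy + ky;
              double *drow = dst + ((R_xlen_t)iz * oy + iy) * ox;
              if (zz < 0 || zz >= Z || yy < 0 || yy >= Y) {
                std::memset(drow, 0, sizeof(double) * ox);
                continue;
              }
              const double *src = xc + ((R_xlen_t)zz * Y + yy) * X;
              if (sx == 1) {
                const int lo = (kx < 0) ? 1 : 0;
                const int hi = (kx > 0) ? ox - 1 : ox;
                if (lo) drow[0] = 0.0;
                if (hi < ox) drow[ox - 1] = 0.0;
                std::memcpy(drow + lo, src + lo + kx, sizeof(double) * (hi - lo));
              } else {
                for (int ix = 0; ix < ox; ++ix) {
                  const int xx = ix * sx + kx;
                  drow[ix] = (xx < 0 || xx >= X) ? 0.0 : src[xx];
                }
              }
            }
          }
        }
  }
}

// y (nout x cout) = im2col(x) %*% Wm + bias
// [[Rcpp::export(name = ".cpp_conv3_fw")]]
NumericVector cpp_conv3_fw(NumericVector x, IntegerVector dims, IntegerVector stride,
                           NumericMatrix Wm, NumericVector bias) {
  const int K = Wm.nrow(), cout = Wm.ncol();
  const int ox = out_extent(dims[0], stride[0]);
  const int oy = out_extent(dims[1], stride[1]);
  const int oz = out_extent(dims[2], stride[2]);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  if ((R_xlen_t)g_col_buf.size() < nout * K) g_col_buf.resize(nout * K);
  im2col_into(g_col_buf.data(), x.begin(), dims.begin(), stride.begin());
  NumericVector y(no_init(nout * cout));
  const int m = (int)nout;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &cout, &K, &one, g_col_buf.data(), &m,
                  Wm.begin(), &K, &zero, y.begin(), &m FCONE FCONE);
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    const double b = bias[co];
    double *col = py + (R_xlen_t)co * nout;
    for (R_xlen_t i = 0; i < nout; ++i) col[i] += b;
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return y;
}

// Backward: rebuild the column matrix, then
//   dW = col^T %*% gy, db = colSums(gy), dx = col2im(gy %*% Wm^T)
// [[Rcpp::export(name = ".cpp_conv3_bw")]]
List cpp_conv3_bw(NumericVector x, IntegerVector dims, IntegerVector stride,
                  NumericMatrix Wm, NumericVector gy) {
  const int K = Wm.nrow(), cout = Wm.ncol();
  const int ox = out_extent(dims[0], stride[0]);
  const int oy = out_extent(dims[1], stride[1]);
  const int oz = out_extent(dims[2], stride[2]);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  if ((R_xlen_t)g_col_buf.size() < nout * K) g_col_buf.resize(nout * K);
  if ((R_xlen_t)g_aux_buf.size() < nout * K) g_aux_buf.resize(nout * K);
  im2col_into(g_col_buf.data(), x.begin(), dims.begin(), stride.begin());
  NumericMatrix dW(no_init(K, cout));
  const int m = (int)nout;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &K, &cout, &m, &one, g_col_buf.data(), &m,
                  gy.begin(), &m, &zero, dW.begin(), &K FCONE FCONE);
  NumericVector db(cout);
  const double *pg = gy.begin();
  for (int co = 0; co < cout; ++co) {
    double s = 0.0;
    const double *col = pg + (R_xlen_t)co * nout;
    for (R_xlen_t i = 0; i < nout; ++i) s += col[i];
    db[co] = s;
  }
  // dxcol = gy %*% Wm^T  (nout x K), into the auxiliary buffer
  F77_CALL(dgemm)("N", "T", &m, &K, &cout, &one, gy.begin(), &m,
                  Wm.begin(), &K, &zero, g_aux_buf.data(), &m FCONE FCONE);
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  // col2im accumulate (adjoint of im2col_into)
  {
    const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
    const int sx = stride[0], sy = stride[1], sz = stride[2];
    double *px = dx.begin();
    const double *pc = g_aux_buf.data();
    for (int c = 0; c < C; ++c) {
      double *xc = px + (R_xlen_t)c * X * Y * Z;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int kidx = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
            const double *src = pc + (R_xlen_t)kidx * nout;
            for (int iz = 0; iz < oz; ++iz) {
              const int zz = iz * sz + kz;
              if (zz < 0 || zz >= Z) continue;
              for (int iy = 0; iy < oy; ++iy) {
                const int yy = iy * sy + ky;
                if (yy < 0 || yy >= Y) continue;
                const double *srow = src + ((R_xlen_t)iz * oy + iy) * ox;
                double *drow = xc + ((R_xlen_t)zz * Y + yy) * X;
                if (sx == 1) {
                  const int lo = (kx < 0) ? 1 : 0;
                  const int hi = (kx > 0) ? ox - 1 : ox;
                  double *d = drow + lo + kx;
                  const double *s = srow + lo;
                  const int n = hi - lo;
                  for (int i = 0; i < n; ++i) d[i] += s[i];
                } else {
                  for (int ix = 0; ix < ox; ++ix) {
                    const int xx = ix * sx + kx;
                    if (xx >= 0 && xx < X) drow[xx] += srow[ix];
                  }
                }
              }
            }
          }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Max pooling with per-axis factors; extents must be divisible by the
// factors (the network pads inputs up front). Returns pooled values plus
// 1-based argmax positions into the flattened input for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool3")]]
List cpp_maxpool3(NumericVector x, IntegerVector dims, IntegerVector f) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = X / fx, oy = Y / fy, oz = Z / fz;
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz * C;
  NumericVector y(no_init(nout));
  IntegerVector idx(no_init(nout));
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * X * Y * Z;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                const R_xlen_t li = coff +
                  ((R_xlen_t)(iz * fz + dz) * Y + (iy * fy + dy)) * X +
                  (ix * fx + dx);
                if (px[li] > best) { best = px[li]; bi = li; }
              }
          y[o] = best;
          idx[o] = (int)(bi + 1);
          ++o;
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large tensors (im2col matrices, feature maps) are allocated and freed at
// high frequency during training. With glibc's defaults every such buffer
// is mmap'ed and unmapped again, so each reuse pays page-fault cost; keep
// big allocations inside the heap arena instead so pages are recycled.
// [[Rcpp::export(name = ".cpp_tune_allocator")]]
bool cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
  return true;
#else
  return false;
#endif
}
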