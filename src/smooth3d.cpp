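#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable 3-D Gaussian convolution on a dense array.
// sigma is in voxel units per axis; kernel truncated at 4 sigma and
// normalised to unit mass.  border = 0 -> reflect, 1 -> zero padding.
static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int R = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int i = -R; i <= R; ++i) {
    double v = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    k[i + R] = v;
    s += v;
  }
  for (double &v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  // scipy-style 'reflect' (mirror about edge, edge value repeated)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void conv_axis(std::vector<double> &a, int nx, int ny, int nz,
                      int axis, const std::vector<double> &k, int border) {
  int R = ((int)k.size() - 1) / 2;
  if (R == 0) return;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(n), out(n);
  long sx = 1, sy = nx, sz = (long)nx * ny;
  long stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  long st1 = axis == 0 ? sy : sx;
  long st2 = axis == 2 ? sy : sz;
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      long base = j1 * st1 + j2 * st2;
      for (int i = 0; i < n; ++i) line[i] = a[base + i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = -R; t <= R; ++t) {
          int src = i + t;
          double v;
          if (src < 0 || src >= n)
            v = border == 1 ? 0.0 : line[reflect_idx(src, n)];
          else
            v = line[src];
          acc += v * k[t + R];
        }
        out[i] = acc;
      }
      for (int i = 0; i < n; ++i) a[base + i * stride] = out[i];
    }
  }
}

// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector arr, IntegerVector dim,
                           NumericVector sigma_vox, int border = 0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox.size() == 3 ? sigma_vox[ax] : sigma_vox[0];
    std::vector<double> k = gauss_kernel(s);
    conv_axis(a, nx, ny, nz, ax, k, border);
  }
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = dim;
  return res;
}

// Smooth every volume of a time x voxel matrix (t rows, voxels in array
// order, column-major storage so each voxel's time series is contiguous).
// All volumes are convolved together, axis by axis, with vectorised
// accumulation over the contiguous time dimension for cache locality.
static void conv_axis_4d(double *a, int nt, int nx, int ny, int nz,
                         int axis, const std::vector<double> &k, int border) {
  int R = ((int)k.size() - 1) / 2;
  if (R == 0) return;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  long vx = 1, vy = nx, vz = (long)nx * ny;        // voxel strides
  long stride = (axis == 0 ? vx : (axis == 1 ? vy : vz)) * nt;
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  long st1 = (axis == 0 ? vy : vx) * nt;
  long st2 = (axis == 2 ? vy : vz) * nt;
  std::vector<double> buf((size_t)n * nt);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      double *base = a + j1 * st1 + j2 * st2;
      for (int i = 0; i < n; ++i)
        std::copy(base + i * stride, base + i * stride + nt,
                  buf.begin() + (size_t)i * nt);
      for (int i = 0; i < n; ++i) {
        double *out = base + i * stride;
        std::fill(out, out + nt, 0.0);
        for (int t = -R; t <= R; ++t) {
          int src = i + t;
          if (src < 0 || src >= n) {
            if (border == 1) continue;
            src = reflect_idx(src, n);
          }
          const double *in = buf.data() + (size_t)src * nt;
          double kv = k[t + R];
          for (int s = 0; s < nt; ++s) out[s] += kv * in[s];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".smooth4d_cpp")]]
NumericMatrix smooth4d_cpp(NumericMatrix tsmat, IntegerVector dim,
                           NumericVector sigma_vox, int border = 0) {
  int nt = tsmat.nrow();
  long nv = (long)dim[0] * dim[1] * dim[2];
  if ((long)tsmat.ncol() != nv) stop("voxel count mismatch");
  NumericMatrix out(Rcpp::clone(tsmat));
  for (int ax = 0; ax < 3; ++ax) {
    std::vector<double> k =
      gauss_kernel(sigma_vox.size() == 3 ? sigma_vox[ax] : sigma_vox[0]);
    conv_axis_4d(REAL(out), nt, dim[0], dim[1], dim[2], ax, k, border);
  }
  return out;
}
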