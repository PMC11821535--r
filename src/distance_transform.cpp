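#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D lower-envelope distance transform of a sampled function (Felzenszwalb &
// Huttenlocher, 2012) on a grid with physical spacing `step`:
//   d[q] = min_i ( step^2 * (q - i)^2 + f[i] )
// Exact up to floating point for arbitrary finite f.
static void dt1d(const double* f, int n, double step, double* d,
                 int* v, double* z) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (k > 0 && s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = step * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared 3D Euclidean distance from every voxel (z, y, x) (z fastest, as in
// an R array of dim c(nz, ny, nx)) to the surface point set
// { (h(y,x), y*dy, x*dx) }, with the depth of plane k equal to k*dz (µm).
// `height` must be finite everywhere (interpolate missing columns first).
// [[Rcpp::export]]
NumericVector surface_sqdist_cpp(NumericMatrix height, int nz,
                                 double dz, double dy, double dx) {
  const int ny = height.nrow(), nx = height.ncol();
  const int m = std::max(nx, ny);
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);

  std::vector<double> f(m), d(m), zz(m + 1);
  std::vector<int> v(m);

  // pass 1: for each (z, y), transform along x of f(x') = (z*dz - h(y,x'))^2
  for (int y = 0; y < ny; ++y) {
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) {
        const double dv = z * dz - height(y, x);
        f[x] = dv * dv;
      }
      dt1d(f.data(), nx, dx, d.data(), v.data(), zz.data());
      for (int x = 0; x < nx; ++x)
        out[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[x];
    }
  }

  // pass 2: transform along y
  for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y)
        f[y] = out[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f.data(), ny, dy, d.data(), v.data(), zz.data());
      for (int y = 0; y < ny; ++y)
        out[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[y];
    }
  }
  return out;
}
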