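#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Separable exact squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher), generalised to anisotropic sample
// spacing h along each axis.  Input f holds current squared distances;
// output d is the lower envelope of parabolas rooted at the samples.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = q * h;
    double s;
    while (true) {
      double vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * h;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every TRUE voxel to the nearest
// FALSE voxel, on a regular grid with per-axis spacing (mm).  Voxels
// outside the grid are treated as foreground (no wrap-around): a
// foreground voxel at the array border measures distance to the nearest
// in-grid background voxel only.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20;
  std::vector<double> g((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) g[(size_t)i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;

  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (size_t)y * nx] = d[y];
    }

  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (size_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (size_t)z * nx * ny] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = g[(size_t)i];
    out[i] = (v >= BIG) ? R_PosInf : std::sqrt(v);
  }
  return out;
}
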