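// Exact Euclidean distance transform of a 3-D voxel mask, computed with
// the separable lower-envelope-of-parabolas algorithm applied along each
// axis in turn.  Supports anisotropic voxel spacing; distances are
// returned in physical units (mm) to the nearest mask voxel (0 inside).

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

static const double DT_INF = std::numeric_limits<double>::infinity();

// One-dimensional squared distance transform along positions x_i = i*h.
// Infinite source values (no mask voxel in that line yet) are excluded
// from the parabola envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  int q0 = 0;
  while (q0 < n && f[q0] == DT_INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = DT_INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == DT_INF) continue;
    double s;
    while (true) {
      const double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * h;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt_cpp(const Rcpp::LogicalVector& mask,
                            const Rcpp::IntegerVector& dims,
                            const Rcpp::NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> g(nv);
  for (R_xlen_t i = 0; i < nv; ++i) g[i] = mask[i] ? 0.0 : DT_INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // x axis (fastest varying)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t off = static_cast<R_xlen_t>(z) * nx * ny +
                           static_cast<R_xlen_t>(y) * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[off + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[off + x] = d[x];
    }
  // y axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t off = static_cast<R_xlen_t>(z) * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[off + static_cast<R_xlen_t>(y) * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[off + static_cast<R_xlen_t>(y) * nx] = d[y];
    }
  // z axis
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t off = static_cast<R_xlen_t>(y) * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[off + static_cast<R_xlen_t>(z) * nxy];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[off + static_cast<R_xlen_t>(z) * nxy] = d[z];
    }

  Rcpp::NumericVector out(nv);
  for (R_xlen_t i = 0; i < nv; ++i)
    out[i] = (g[i] == DT_INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
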