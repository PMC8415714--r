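#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over the three axes. Input: binary mask; output: for each TRUE
// voxel, squared distance (in voxel units, center-to-center) to the nearest
// FALSE voxel center; 0 elsewhere. A grid with no FALSE voxel returns +Inf.

// Large finite sentinel standing in for +infinity: squared grid distances
// are < 1e12 for any realistic volume, so the sentinel always dominates.
static const double BIG = 1e30;

static void dt1d(const double *f, double *d, int n, std::vector<int> &v,
                 std::vector<double> &zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -BIG;
  zbuf[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zbuf[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, v, zbuf);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * (R_xlen_t)ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f.data(), d.data(), ny, v, zbuf);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + nxy * z];
      dt1d(f.data(), d.data(), nz, v, zbuf);
      for (int z = 0; z < nz; ++z) out[base + nxy * z] = d[z];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= 1e29) out[i] = R_PosInf;
  out.attr("dim") = dim;
  return out;
}
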