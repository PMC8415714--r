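#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential placement of spherical pore objects into a voxel grid.
// Candidates (center in 0-based voxel coordinates + radius in voxels) are
// consumed in order; a candidate is placed when its ball (voxel-center-in-
// sphere rule) lies fully inside `region` with a 1-voxel border margin and,
// for non-overlapping placement, no voxel within radius+clearance is already
// occupied (1.8 voxels > sqrt(3) rules out any 26-adjacency). Placement stops when the running pore-voxel total would overshoot
// `target_voxels` by more than half of the next object's contribution, or
// when `target_objects` objects have been placed.
// [[Rcpp::export]]
List place_spheres_cpp(IntegerVector dim, LogicalVector region,
                       NumericVector cx, NumericVector cy, NumericVector cz,
                       NumericVector r_vox, bool allow_overlap,
                       double clearance, double target_voxels,
                       int target_objects) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (region.size() != n) stop("region length does not match dim");
  const int ncand = cx.size();

  IntegerVector pore(n, 0);
  std::vector<int> placed_idx;
  std::vector<int> voxel_counts;
  std::vector<R_xlen_t> ball;
  double total = 0.0;
  bool target_reached = (target_voxels > 0 && target_voxels < 0.5);

  for (int i = 0; i < ncand && !target_reached; ++i) {
    const double x0 = cx[i], y0 = cy[i], z0 = cz[i], r = r_vox[i];
    const double rc = allow_overlap ? r : r + clearance;
    const int xlo = (int)std::floor(x0 - rc), xhi = (int)std::ceil(x0 + rc);
    const int ylo = (int)std::floor(y0 - rc), yhi = (int)std::ceil(y0 + rc);
    const int zlo = (int)std::floor(z0 - rc), zhi = (int)std::ceil(z0 + rc);
    if (xlo < 1 || ylo < 1 || zlo < 1 ||
        xhi > nx - 2 || yhi > ny - 2 || zhi > nz - 2) continue;

    ball.clear();
    bool ok = true;
    const double r2 = r * r, rc2 = rc * rc;
    for (int z = zlo; z <= zhi && ok; ++z)
      for (int y = ylo; y <= yhi && ok; ++y)
        for (int x = xlo; x <= xhi && ok; ++x) {
          const double dd = (x - x0) * (x - x0) + (y - y0) * (y - y0) +
                            (z - z0) * (z - z0);
          if (dd > rc2) continue;
          R_xlen_t j = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (dd <= r2) {
            if (!region[j]) { ok = false; break; }
            ball.push_back(j);
          }
          if (!allow_overlap && pore[j] != 0) { ok = false; break; }
        }
    if (!ok || ball.empty()) continue;

    int newv = 0;
    for (size_t k = 0; k < ball.size(); ++k)
      if (pore[ball[k]] == 0) ++newv;
    if (target_voxels > 0 && total + newv / 2.0 > target_voxels) {
      target_reached = true;
      break;
    }
    const int id = (int)placed_idx.size() + 1;
    for (size_t k = 0; k < ball.size(); ++k)
      if (pore[ball[k]] == 0) pore[ball[k]] = id;
    placed_idx.push_back(i + 1);  // 1-based candidate index
    voxel_counts.push_back(newv);
    total += newv;
    if (target_objects > 0 && (int)placed_idx.size() >= target_objects)
      target_reached = true;
  }

  pore.attr("dim") = dim;
  return List::create(_["labels"] = pore,
                      _["placed"] = wrap(placed_idx),
                      _["voxel_count"] = wrap(voxel_counts),
                      _["total_voxels"] = total,
                      _["target_reached"] = target_reached);
}

// Surface area of a binary object from exposed voxel faces. Each face
// between an object voxel and a background voxel contributes
// h^2 * |n|_2 / |n|_1, where n is the outward normal estimated from the
// gradient of a box-smoothed (radius 2) copy of the mask. The weighting is
// exact for planar interfaces of any orientation.
// [[Rcpp::export]]
double surface_area_cpp(LogicalVector mask, IntegerVector dim, double h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  // separable box smoothing, radius 2, clamped at borders
  std::vector<double> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 1.0 : 0.0;
  const int rad = 2;
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0; int c = 0;
        for (int k = -rad; k <= rad; ++k) {
          int xx = x + k;
          if (xx < 0 || xx >= nx) continue;
          s += a[xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]; ++c;
        }
        b[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = s / c;
      }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double s = 0; int c = 0;
        for (int k = -rad; k <= rad; ++k) {
          int yy = y + k;
          if (yy < 0 || yy >= ny) continue;
          s += b[x + (R_xlen_t)nx * (yy + (R_xlen_t)ny * z)]; ++c;
        }
        a[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = s / c;
      }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        double s = 0; int c = 0;
        for (int k = -rad; k <= rad; ++k) {
          int zz = z + k;
          if (zz < 0 || zz >= nz) continue;
          s += a[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz)]; ++c;
        }
        b[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = s / c;
      }

  auto G = [&](int x, int y, int z) -> double {
    if (x < 0) x = 0; if (x >= nx) x = nx - 1;
    if (y < 0) y = 0; if (y >= ny) y = ny - 1;
    if (z < 0) z = 0; if (z >= nz) z = nz - 1;
    return b[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto grad = [&](int x, int y, int z, double g[3]) {
    g[0] = (G(x + 1, y, z) - G(x - 1, y, z)) / 2.0;
    g[1] = (G(x, y + 1, z) - G(x, y - 1, z)) / 2.0;
    g[2] = (G(x, y, z + 1) - G(x, y, z - 1)) / 2.0;
  };

  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[i]) continue;
        for (int k = 0; k < 6; ++k) {
          int xx = x + d6[k][0], yy = y + d6[k][1], zz = z + d6[k][2];
          bool bg = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) ||
                    !mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (!bg) continue;
          double g1[3], g2[3];
          grad(x, y, z, g1);
          grad(xx, yy, zz, g2);
          double gx = (g1[0] + g2[0]) / 2.0, gy = (g1[1] + g2[1]) / 2.0,
                 gz = (g1[2] + g2[2]) / 2.0;
          double l1 = std::fabs(gx) + std::fabs(gy) + std::fabs(gz);
          double l2 = std::sqrt(gx * gx + gy * gy + gz * gz);
          area += (l1 < 1e-12) ? 1.0 : (l2 / l1);
        }
      }
  return area * h * h;
}
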