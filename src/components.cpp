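#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D voxel grid helpers. Linear index follows R column-major order:
// idx = x + nx*(y + ny*z), all 0-based here.

static inline void decode(int idx, int nx, int ny, int &x, int &y, int &z) {
  x = idx % nx;
  int r = idx / nx;
  y = r % ny;
  z = r / ny;
}

// Connected-component labeling of a binary 3D field.
// connectivity 6 (face) or 26 (face, edge or corner).
// Labels are assigned in ascending order of each component's first voxel
// in linear scan order, so the id order is deterministic.
// [[Rcpp::export]]
List label_components_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;

  // neighbor offsets
  int dxs[26], dys[26], dzs[26], nn = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs[nn] = dx; dys[nn] = dy; dzs[nn] = dz; ++nn;
      }

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x, y, z; decode(cur, nx, ny, x, y, z);
      for (int k = 0; k < nn; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back((int)j);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels, _["n"] = next);
}

// Fill enclosed cavities of a binary object: flood the background
// 6-connected from the grid border; anything not reached becomes object.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> outside(n, 0);
  std::vector<int> stack;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) continue;
    int x, y, z; decode((int)i, nx, ny, x, y, z);
    if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1) {
      if (!outside[i]) { outside[i] = 1; stack.push_back((int)i); }
    }
  }
  const int fdx[6] = {1,-1,0,0,0,0}, fdy[6] = {0,0,1,-1,0,0}, fdz[6] = {0,0,0,0,1,-1};
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int x, y, z; decode(cur, nx, ny, x, y, z);
    for (int k = 0; k < 6; ++k) {
      int xx = x + fdx[k], yy = y + fdy[k], zz = z + fdz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back((int)j); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Per-voxel count of 26-neighbors that are object.
// [[Rcpp::export]]
IntegerVector neighbor_count26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector out(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x, y, z; decode((int)i, nx, ny, x, y, z);
    int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          if (mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) ++cnt;
        }
    out[i] = cnt;
  }
  out.attr("dim") = dim;
  return out;
}
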