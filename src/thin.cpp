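#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving 3D thinning for a (26,6) digital picture:
// the object is 26-connected, the background 6-connected. A voxel is
// *simple* (deletable without changing topology) iff
//   T26 = number of 26-components of object voxels in N26*(p) == 1, and
//   T6  = number of 6-components of background voxels in N18(p) that are
//         6-adjacent to p == 1
// (Bertrand & Malandain characterization). Directional subiterations
// (borders stripped one face direction at a time) with sequential
// re-checking give a centered, unbiased curve skeleton; endpoints of
// 1-voxel-wide curves are preserved so tubular structures keep their
// full extent.

// neighborhood occupancy: nb[dz+1][dy+1][dx+1], outside grid = 0 (background)
static inline void load_nb(const int *m, int nx, int ny, int nz,
                           int x, int y, int z, int nb[3][3][3]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          nb[dz + 1][dy + 1][dx + 1] = 0;
        else
          nb[dz + 1][dy + 1][dx + 1] =
            m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] ? 1 : 0;
      }
}

// number of 26-connected components of object voxels in the 26-neighborhood
static int t26(const int nb[3][3][3]) {
  int seen[3][3][3] = {{{0}}};
  int ncomp = 0;
  int stack[26][3];
  for (int z0 = 0; z0 < 3; ++z0)
    for (int y0 = 0; y0 < 3; ++y0)
      for (int x0 = 0; x0 < 3; ++x0) {
        if (z0 == 1 && y0 == 1 && x0 == 1) continue;
        if (!nb[z0][y0][x0] || seen[z0][y0][x0]) continue;
        ++ncomp;
        int top = 0;
        stack[top][0] = x0; stack[top][1] = y0; stack[top][2] = z0; ++top;
        seen[z0][y0][x0] = 1;
        while (top > 0) {
          --top;
          int cx = stack[top][0], cy = stack[top][1], cz = stack[top][2];
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
                if (xx == 1 && yy == 1 && zz == 1) continue;
                if (nb[zz][yy][xx] && !seen[zz][yy][xx]) {
                  seen[zz][yy][xx] = 1;
                  stack[top][0] = xx; stack[top][1] = yy; stack[top][2] = zz; ++top;
                }
              }
        }
      }
  return ncomp;
}

// number of 6-connected components of *background* voxels within the
// 18-neighborhood (face+edge neighbors) that contain a face neighbor of p
static int t6(const int nb[3][3][3]) {
  int seen[3][3][3] = {{{0}}};
  int ncomp = 0;
  int stack[18][3];
  static const int faces[6][3] = {
    {0,1,1},{2,1,1},{1,0,1},{1,2,1},{1,1,0},{1,1,2}};
  for (int fi = 0; fi < 6; ++fi) {
    int x0 = faces[fi][0], y0 = faces[fi][1], z0 = faces[fi][2];
    if (nb[z0][y0][x0] || seen[z0][y0][x0]) continue;
    ++ncomp;
    int top = 0;
    stack[top][0] = x0; stack[top][1] = y0; stack[top][2] = z0; ++top;
    seen[z0][y0][x0] = 1;
    while (top > 0) {
      --top;
      int cx = stack[top][0], cy = stack[top][1], cz = stack[top][2];
      static const int f6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + f6[k][0], yy = cy + f6[k][1], zz = cz + f6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        if (xx == 1 && yy == 1 && zz == 1) continue;
        // restrict to the 18-neighborhood: exclude the 8 corners
        int off = std::abs(xx - 1) + std::abs(yy - 1) + std::abs(zz - 1);
        if (off > 2) continue;
        if (!nb[zz][yy][xx] && !seen[zz][yy][xx]) {
          seen[zz][yy][xx] = 1;
          stack[top][0] = xx; stack[top][1] = yy; stack[top][2] = zz; ++top;
        }
      }
    }
  }
  return ncomp;
}

static inline int nb_count(const int nb[3][3][3]) {
  int c = 0;
  for (int z = 0; z < 3; ++z)
    for (int y = 0; y < 3; ++y)
      for (int x = 0; x < 3; ++x) {
        if (x == 1 && y == 1 && z == 1) continue;
        c += nb[z][y][x];
      }
  return c;
}

static inline bool deletable(const int *m, int nx, int ny, int nz,
                             int x, int y, int z) {
  int nb[3][3][3];
  load_nb(m, nx, ny, nz, x, y, z, nb);
  int cnt = nb_count(nb);
  if (cnt <= 1) return false;            // isolated voxel or curve endpoint
  if (t26(nb) != 1) return false;
  if (t6(nb) != 1) return false;
  return true;
}

// [[Rcpp::export]]
LogicalVector thin_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  std::vector<int> m(n);
  std::vector<R_xlen_t> object;
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = mask[i] ? 1 : 0;
    if (m[i]) object.push_back(i);
  }

  static const int dirs[6][3] = {
    {0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t oi = 0; oi < object.size(); ++oi) {
        R_xlen_t i = object[oi];
        if (!m[i]) continue;
        int x = (int)(i % nx);
        int r = (int)(i / nx);
        int y = r % ny, z = r / ny;
        int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
        bool border;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          border = true;
        else
          border = !m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        if (!border) continue;
        if (deletable(m.data(), nx, ny, nz, x, y, z)) cand.push_back(i);
      }
      // sequential deletion with re-check keeps every removal simple
      for (size_t k = 0; k < cand.size(); ++k) {
        R_xlen_t i = cand[k];
        int x = (int)(i % nx);
        int r = (int)(i / nx);
        int y = r % ny, z = r / ny;
        if (deletable(m.data(), nx, ny, nz, x, y, z)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
    // compact the object list
    size_t w = 0;
    for (size_t oi = 0; oi < object.size(); ++oi)
      if (m[object[oi]]) object[w++] = object[oi];
    object.resize(w);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
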