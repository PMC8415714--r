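#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volume of the 3D convex hull of a point set, by incremental hull
// construction (visible-face deletion + horizon re-triangulation).
// Intended for modest point counts (callers reduce voxel clouds to
// per-slice extreme points first). Degenerate (coplanar) inputs return 0.

struct Face { int a, b, c; bool alive; };

static inline void sub(const double *p, const double *q, double *r) {
  r[0] = p[0] - q[0]; r[1] = p[1] - q[1]; r[2] = p[2] - q[2];
}
static inline void cross(const double *u, const double *v, double *w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}
static inline double dot(const double *u, const double *v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

// signed distance factor of point p above plane of face (a,b,c)
static double orient(const std::vector<double> &P, int a, int b, int c, int p) {
  double u[3], v[3], w[3], nrm[3];
  sub(&P[3 * b], &P[3 * a], u);
  sub(&P[3 * c], &P[3 * a], v);
  cross(u, v, nrm);
  sub(&P[3 * p], &P[3 * a], w);
  return dot(nrm, w);
}

// [[Rcpp::export]]
double convex_hull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> P(3 * n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pts(i, 0); P[3 * i + 1] = pts(i, 1); P[3 * i + 2] = pts(i, 2);
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(pts(i, k)));
  }
  if (scale == 0) scale = 1.0;
  const double eps = 1e-9 * scale * scale * scale;

  // initial tetrahedron from extreme points
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d[3]; sub(&P[3 * i], &P[3 * i0], d);
    double dd = dot(d, d);
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= 0) return 0.0;
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double u[3], v[3], w[3];
    sub(&P[3 * i1], &P[3 * i0], u);
    sub(&P[3 * i], &P[3 * i0], v);
    cross(u, v, w);
    double dd = dot(w, w);
    if (dd > best) { best = dd; i2 = i; }
  }
  if (i2 < 0 || best <= 0) return 0.0;
  int i3 = -1; best = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double o = orient(P, i0, i1, i2, i);
    if (std::fabs(o) > std::fabs(best)) { best = o; i3 = i; }
  }
  if (i3 < 0 || std::fabs(best) <= eps) return 0.0;  // coplanar cloud
  if (best > 0) std::swap(i1, i2);  // make i3 lie below (a,b,c)

  std::vector<Face> faces;
  faces.push_back({i0, i1, i2, true});
  faces.push_back({i0, i3, i1, true});
  faces.push_back({i1, i3, i2, true});
  faces.push_back({i2, i3, i0, true});

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // find visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient(P, faces[f].a, faces[f].b, faces[f].c, p) > eps)
        vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // inside current hull
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face &F = faces[vis[k]];
      int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (int j = 0; j < 3; ++j) {
        bool shared = false;
        // edge (v,u) belongs to another visible face?
        for (size_t k2 = 0; k2 < vis.size() && !shared; ++k2) {
          if (k2 == k) continue;
          const Face &G = faces[vis[k2]];
          int g[3][2] = {{G.a, G.b}, {G.b, G.c}, {G.c, G.a}};
          for (int j2 = 0; j2 < 3; ++j2)
            if (g[j2][0] == e[j][1] && g[j2][1] == e[j][0]) { shared = true; break; }
        }
        if (!shared) edges.push_back(std::make_pair(e[j][0], e[j][1]));
      }
    }
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    for (size_t k = 0; k < edges.size(); ++k)
      faces.push_back({edges[k].first, edges[k].second, p, true});
  }

  // volume via signed tetrahedra against the centroid
  double c0[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) c0[k] += P[3 * i + k] / n;
  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    double u[3], v[3], w[3], x[3];
    sub(&P[3 * faces[f].a], c0, u);
    sub(&P[3 * faces[f].b], c0, v);
    sub(&P[3 * faces[f].c], c0, w);
    cross(v, w, x);
    vol += dot(u, x) / 6.0;
  }
  return std::fabs(vol);
}
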