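#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull. Points are inserted farthest-first; each
// point outside the current hull removes the faces it can see and fills
// the horizon with a cone of new faces. Points within tol of a face plane
// count as interior, which collapses the many coplanar corners of
// rasterized voxel grids. O(n * faces), no conflict lists -- fast enough
// for the corner clouds this package produces.

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // outward unit normal, plane offset
  bool alive;
};

static bool make_plane(const std::vector<double> &px, const std::vector<double> &py,
                       const std::vector<double> &pz, int a, int b, int c,
                       const double inter[3], Face &f) {
  double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
  double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double ln = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (ln < 1e-300) return false;
  nx /= ln; ny /= ln; nz /= ln;
  double off = nx * px[a] + ny * py[a] + nz * pz[a];
  if (nx * inter[0] + ny * inter[1] + nz * inter[2] > off) {
    nx = -nx; ny = -ny; nz = -nz; off = -off;
    std::swap(f.b, f.c);
  }
  f.a = a; f.b = b; f.c = c;
  f.nx = nx; f.ny = ny; f.nz = nz; f.off = off;
  f.alive = true;
  return true;
}

// [[Rcpp::export]]
List quickhull3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> px(n), py(n), pz(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    lo[0] = std::min(lo[0], px[i]); hi[0] = std::max(hi[0], px[i]);
    lo[1] = std::min(lo[1], py[i]); hi[1] = std::max(hi[1], py[i]);
    lo[2] = std::min(lo[2], pz[i]); hi[2] = std::max(hi[2], pz[i]);
  }
  double scale = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0});
  double tol = 1e-9 * scale;

  // initial tetrahedron from extremes
  int i1 = 0;
  for (int i = 1; i < n; ++i) if (px[i] < px[i1]) i1 = i;
  int i2 = 0; double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = (px[i] - px[i1]) * (px[i] - px[i1]) +
               (py[i] - py[i1]) * (py[i] - py[i1]) +
               (pz[i] - pz[i1]) * (pz[i] - pz[i1]);
    if (d > best) { best = d; i2 = i; }
  }
  double ax = px[i2] - px[i1], ay = py[i2] - py[i1], az = pz[i2] - pz[i1];
  int i3 = 0; best = -1;
  for (int i = 0; i < n; ++i) {
    double wx = px[i] - px[i1], wy = py[i] - py[i1], wz = pz[i] - pz[i1];
    double cx = wy * az - wz * ay, cy = wz * ax - wx * az, cz = wx * ay - wy * ax;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i3 = i; }
  }
  double bx = px[i3] - px[i1], by = py[i3] - py[i1], bz = pz[i3] - pz[i1];
  double nx0 = ay * bz - az * by, ny0 = az * bx - ax * bz, nz0 = ax * by - ay * bx;
  int i4 = 0; best = -1;
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(nx0 * (px[i] - px[i1]) + ny0 * (py[i] - py[i1]) +
                         nz0 * (pz[i] - pz[i1]));
    if (h > best) { best = h; i4 = i; }
  }
  double nlen = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
  if (nlen < 1e-300 ||
      best / nlen <= tol) stop("point set is degenerate (coplanar); no 3D hull");

  double inter[3] = {
    (px[i1] + px[i2] + px[i3] + px[i4]) / 4.0,
    (py[i1] + py[i2] + py[i3] + py[i4]) / 4.0,
    (pz[i1] + pz[i2] + pz[i3] + pz[i4]) / 4.0
  };

  std::vector<Face> faces;
  faces.reserve(256);
  {
    int tetra[4][3] = {{i1, i2, i3}, {i1, i2, i4}, {i1, i3, i4}, {i2, i3, i4}};
    for (auto &t : tetra) {
      Face f;
      if (make_plane(px, py, pz, t[0], t[1], t[2], inter, f)) faces.push_back(f);
    }
  }

  // farthest-first insertion order
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != i1 && i != i2 && i != i3 && i != i4) order.push_back(i);
  std::sort(order.begin(), order.end(), [&](int u, int v) {
    double du = (px[u] - inter[0]) * (px[u] - inter[0]) +
                (py[u] - inter[1]) * (py[u] - inter[1]) +
                (pz[u] - inter[2]) * (pz[u] - inter[2]);
    double dv = (px[v] - inter[0]) * (px[v] - inter[0]) +
                (py[v] - inter[1]) * (py[v] - inter[1]) +
                (pz[v] - inter[2]) * (pz[v] - inter[2]);
    return du > dv;
  });

  std::vector<int> visible;
  std::map<std::pair<int, int>, std::pair<int, int>> edges;  // edge -> count, orient
  for (int p : order) {
    visible.clear();
    for (int fi = 0; fi < (int)faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      double d = faces[fi].nx * px[p] + faces[fi].ny * py[p] +
                 faces[fi].nz * pz[p] - faces[fi].off;
      if (d > tol) visible.push_back(fi);
    }
    if (visible.empty()) continue;
    edges.clear();
    for (int fi : visible) {
      int vv[3] = {faces[fi].a, faces[fi].b, faces[fi].c};
      for (int e = 0; e < 3; ++e) {
        int u = vv[e], w = vv[(e + 1) % 3];
        auto key = std::minmax(u, w);
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = {1, u};
        else it->second.first += 1;
      }
      faces[fi].alive = false;
    }
    for (auto &kv : edges) {
      if (kv.second.first != 1) continue;  // interior edge of the visible patch
      Face f;
      if (make_plane(px, py, pz, kv.first.first, kv.first.second, p, inter, f))
        faces.push_back(f);
    }
    // periodically compact the face list
    if (faces.size() > 4096) {
      std::vector<Face> keep;
      keep.reserve(faces.size() / 2);
      for (auto &f : faces) if (f.alive) keep.push_back(f);
      faces.swap(keep);
    }
  }

  double vol = 0.0;
  std::vector<int> fa, fb, fc;
  std::vector<bool> isv(n, false);
  for (auto &f : faces) {
    if (!f.alive) continue;
    double a1 = px[f.a] - inter[0], a2 = py[f.a] - inter[1], a3 = pz[f.a] - inter[2];
    double b1 = px[f.b] - inter[0], b2 = py[f.b] - inter[1], b3 = pz[f.b] - inter[2];
    double c1 = px[f.c] - inter[0], c2 = py[f.c] - inter[1], c3 = pz[f.c] - inter[2];
    double det = a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
                 a3 * (b1 * c2 - b2 * c1);
    vol += std::fabs(det) / 6.0;
    fa.push_back(f.a + 1); fb.push_back(f.b + 1); fc.push_back(f.c + 1);
    isv[f.a] = isv[f.b] = isv[f.c] = true;
  }
  IntegerVector verts;
  {
    std::vector<int> vs;
    for (int i = 0; i < n; ++i) if (isv[i]) vs.push_back(i + 1);
    verts = wrap(vs);
  }
  IntegerMatrix fm(fa.size(), 3);
  for (size_t i = 0; i < fa.size(); ++i) {
    fm(i, 0) = fa[i]; fm(i, 1) = fb[i]; fm(i, 2) = fc[i];
  }
  return List::create(_["vertex_indices"] = verts, _["faces"] = fm,
                      _["volume"] = vol);
}
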