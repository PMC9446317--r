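#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 6-tetrahedra decomposition of the unit cell around the 0-7 diagonal.
// Cube vertex v in 0..7 sits at (v&1, (v>>1)&1, (v>>2)&1) relative to the
// cell origin.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Total area of the iso-surface of a scalar 3D field, triangulated by
// marching tetrahedra with linear interpolation along tetrahedron edges.
// Spacing-aware: vertex coordinates are voxel indices scaled by spacing (mm).
// The caller is expected to pad the field so the surface closes.
// [[Rcpp::export]]
double mt_surface_area_cpp(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0;

  double pos[8][3], val[8];
  double vert[4][3];  // interpolated crossing points within one tet

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int v = 0; v < 8; ++v) {
          int ii = i + (v & 1), jj = j + ((v >> 1) & 1), kk = k + ((v >> 2) & 1);
          val[v] = vol[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          pos[v][0] = ii * sx; pos[v][1] = jj * sy; pos[v][2] = kk * sz;
          if (val[v] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int inside[4], n_in = 0, outside[4], n_out = 0;
          for (int v = 0; v < 4; ++v) {
            if (val[T[v]] >= iso) inside[n_in++] = T[v];
            else outside[n_out++] = T[v];
          }
          if (n_in == 0 || n_in == 4) continue;

          // crossing point on the edge a-b (a inside, b outside)
          auto cross_pt = [&](int a, int b, double out[3]) {
            double tt = (iso - val[a]) / (val[b] - val[a]);
            for (int d = 0; d < 3; ++d)
              out[d] = pos[a][d] + tt * (pos[b][d] - pos[a][d]);
          };

          if (n_in == 1 || n_in == 3) {
            int apex = (n_in == 1) ? inside[0] : outside[0];
            int *others = (n_in == 1) ? outside : inside;
            for (int m = 0; m < 3; ++m) {
              if (n_in == 1) cross_pt(apex, others[m], vert[m]);
              else cross_pt(others[m], apex, vert[m]);
            }
            area += tri_area(vert[0], vert[1], vert[2]);
          } else {  // 2 in, 2 out: quad on edges AC, AD, BD, BC
            int A = inside[0], B = inside[1], C = outside[0], D = outside[1];
            cross_pt(A, C, vert[0]);
            cross_pt(A, D, vert[1]);
            cross_pt(B, D, vert[2]);
            cross_pt(B, C, vert[3]);
            area += tri_area(vert[0], vert[1], vert[2]);
            area += tri_area(vert[0], vert[2], vert[3]);
          }
        }
      }
  return area;
}

// Separable Gaussian smoothing of a 3D field (sigma in voxels, zero
// boundary). Used to mollify binary masks before iso-surfacing.
// [[Rcpp::export]]
NumericVector smooth3d_cpp(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);

  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int m = -rad; m <= rad; ++m) {
    ker[m + rad] = std::exp(-0.5 * m * m / (sigma * sigma));
    s += ker[m + rad];
  }
  for (double &w : ker) w /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const R_xlen_t str = strides[axis];
    for (R_xlen_t base = 0; base < n; ++base) {
      int idx_along = (int)((base / str) % len);
      double acc = 0.0;
      for (int m = -rad; m <= rad; ++m) {
        int p = idx_along + m;
        if (p < 0 || p >= len) continue;
        acc += ker[m + rad] * a[base + (R_xlen_t)m * str];
      }
      b[base] = acc;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
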