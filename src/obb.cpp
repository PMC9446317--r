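#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Indices (1-based) of the point extreme in each query direction.
// Used to thin voxel-corner clouds before convex-hull and box searches:
// every returned point is a vertex of the convex hull.
// [[Rcpp::export]]
IntegerVector extreme_points_cpp(NumericMatrix pts, NumericMatrix dirs) {
  const int n = pts.nrow(), m = dirs.nrow();
  IntegerVector out(m);
  for (int d = 0; d < m; ++d) {
    double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    double best = -std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int i = 0; i < n; ++i) {
      double s = pts(i, 0) * dx + pts(i, 1) * dy + pts(i, 2) * dz;
      if (s > best) { best = s; arg = i; }
    }
    out[d] = arg + 1;
  }
  return out;
}

// Box orientations are parameterized by one box axis u on the upper
// hemisphere (polar angle beta in [0, 90] deg, azimuth gamma in [0, 360)
// deg) plus an in-plane rotation alpha in [0, 90) deg of the remaining two
// axes. Every frame of three mutually orthogonal (unsigned, unordered)
// axes is reached, so a grid over (beta, gamma, alpha) is an exhaustive
// search over box orientations at that angular resolution.

struct BoxBest {
  double vol;
  double axes[3][3];  // rows are the box axes
};

static void scan_grid(const NumericMatrix &pts, double step_deg, BoxBest &best) {
  const int n = pts.nrow();
  const double d2r = M_PI / 180.0;
  const int nb = (int)std::floor(90.0 / step_deg + 1e-9) + 1;
  const int ng = (int)std::ceil(360.0 / step_deg - 1e-9);
  const int na = (int)std::ceil(90.0 / step_deg - 1e-9);

  std::vector<double> a(n), b(n);
  for (int ib = 0; ib < nb; ++ib) {
    double beta = std::min(90.0, ib * step_deg) * d2r;
    double cb = std::cos(beta), sb = std::sin(beta);
    for (int ig = 0; ig < ng; ++ig) {
      double gamma = ig * step_deg * d2r;
      double cg = std::cos(gamma), sg = std::sin(gamma);
      double u[3]  = {sb * cg, sb * sg, cb};
      double e1[3] = {cb * cg, cb * sg, -sb};
      double e2[3] = {-sg, cg, 0.0};
      double cmin = R_PosInf, cmax = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        a[i] = px * e1[0] + py * e1[1] + pz * e1[2];
        b[i] = px * e2[0] + py * e2[1];
        double c = px * u[0] + py * u[1] + pz * u[2];
        if (c < cmin) cmin = c;
        if (c > cmax) cmax = c;
      }
      double zw = cmax - cmin;
      if (zw * 0.0 != 0.0) continue;
      for (int ia = 0; ia < na; ++ia) {
        double alpha = ia * step_deg * d2r;
        double ca = std::cos(alpha), sa = std::sin(alpha);
        double mn1 = R_PosInf, mx1 = R_NegInf, mn2 = R_PosInf, mx2 = R_NegInf;
        for (int i = 0; i < n; ++i) {
          double w1 = a[i] * ca + b[i] * sa;
          double w2 = -a[i] * sa + b[i] * ca;
          if (w1 < mn1) mn1 = w1;
          if (w1 > mx1) mx1 = w1;
          if (w2 < mn2) mn2 = w2;
          if (w2 > mx2) mx2 = w2;
        }
        double vol = zw * (mx1 - mn1) * (mx2 - mn2);
        if (vol < best.vol) {
          best.vol = vol;
          for (int d = 0; d < 3; ++d) {
            best.axes[0][d] = ca * e1[d] + sa * e2[d];
            best.axes[1][d] = -sa * e1[d] + ca * e2[d];
            best.axes[2][d] = u[d];
          }
        }
      }
    }
  }
}

static List best_to_list(const BoxBest &best) {
  NumericMatrix ax(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) ax(r, c) = best.axes[r][c];
  return List::create(_["volume"] = best.vol, _["axes"] = ax);
}

// Coarse global orientation scan used to seed the production box search.
// [[Rcpp::export]]
List obb_scan_cpp(NumericMatrix pts, double step_deg) {
  BoxBest best;
  best.vol = R_PosInf;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) best.axes[r][c] = (r == c) ? 1.0 : 0.0;
  scan_grid(pts, step_deg, best);
  return best_to_list(best);
}

// Local refinement: grid over small rotations Rx(a)Ry(b)Rz(c) applied to a
// starting frame, |a|,|b|,|c| <= window_deg in steps of step_deg.
// [[Rcpp::export]]
List obb_refine_cpp(NumericMatrix pts, NumericMatrix axes0,
                    double window_deg, double step_deg) {
  const int n = pts.nrow();
  const double d2r = M_PI / 180.0;
  const int half = (int)std::round(window_deg / step_deg);

  BoxBest best;
  best.vol = R_PosInf;

  for (int ia = -half; ia <= half; ++ia)
    for (int ib = -half; ib <= half; ++ib)
      for (int ic = -half; ic <= half; ++ic) {
        double A = ia * step_deg * d2r, B = ib * step_deg * d2r, C = ic * step_deg * d2r;
        double ca = std::cos(A), sa = std::sin(A);
        double cb = std::cos(B), sb = std::sin(B);
        double cc = std::cos(C), sc = std::sin(C);
        // R = Rx(A) Ry(B) Rz(C)
        double R[3][3] = {
          {cb * cc, -cb * sc, sb},
          {ca * sc + sa * sb * cc, ca * cc - sa * sb * sc, -sa * cb},
          {sa * sc - ca * sb * cc, sa * cc + ca * sb * sc, ca * cb}
        };
        // rotate each starting axis: ax_r = R * axes0_r
        double ax[3][3];
        for (int r = 0; r < 3; ++r)
          for (int d = 0; d < 3; ++d)
            ax[r][d] = R[d][0] * axes0(r, 0) + R[d][1] * axes0(r, 1) + R[d][2] * axes0(r, 2);

        double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
        double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
        for (int i = 0; i < n; ++i) {
          double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
          for (int r = 0; r < 3; ++r) {
            double s = px * ax[r][0] + py * ax[r][1] + pz * ax[r][2];
            if (s < mn[r]) mn[r] = s;
            if (s > mx[r]) mx[r] = s;
          }
        }
        double vol = (mx[0] - mn[0]) * (mx[1] - mn[1]) * (mx[2] - mn[2]);
        if (vol < best.vol) {
          best.vol = vol;
          for (int r = 0; r < 3; ++r)
            for (int d = 0; d < 3; ++d) best.axes[r][d] = ax[r][d];
        }
      }
  return best_to_list(best);
}

// Brute-force reference: sweep of the orientation grid over the given
// angle ranges at the given angular resolution (callers use 1 degree
// globally, then re-sweep shrinking windows around the best cell). Kept
// as a plain re-derivation, independent of the production scan/refine
// path.
// [[Rcpp::export]]
List obb_exhaustive_cpp(NumericMatrix pts, double step_deg,
                        double beta_lo, double beta_hi,
                        double gamma_lo, double gamma_hi,
                        double alpha_lo, double alpha_hi) {
  const int n = pts.nrow();
  const double d2r = M_PI / 180.0;
  double best = R_PosInf;
  double best_ang[3] = {0, 0, 0};
  std::vector<double> pa(n), pb(n);

  for (double beta = beta_lo; beta <= beta_hi + 1e-9; beta += step_deg) {
    double th = beta * d2r;
    double ct = std::cos(th), st = std::sin(th);
    for (double gamma = gamma_lo; gamma <= gamma_hi + 1e-9; gamma += step_deg) {
      double ph = gamma * d2r;
      double cp = std::cos(ph), sp = std::sin(ph);
      // axis w and an orthonormal pair (p, q) spanning its normal plane
      double wx = st * cp, wy = st * sp, wz = ct;
      double px_ = ct * cp, py_ = ct * sp, pz_ = -st;
      double qx = -sp, qy = cp, qz = 0.0;
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
        pa[i] = x * px_ + y * py_ + z * pz_;
        pb[i] = x * qx + y * qy + z * qz;
        double w = x * wx + y * wy + z * wz;
        if (w < lo) lo = w;
        if (w > hi) hi = w;
      }
      double wwidth = hi - lo;
      for (double alpha = alpha_lo; alpha <= alpha_hi + 1e-9; alpha += step_deg) {
        double an = alpha * d2r;
        double c = std::cos(an), s = std::sin(an);
        double l1 = R_PosInf, h1 = R_NegInf, l2 = R_PosInf, h2 = R_NegInf;
        for (int i = 0; i < n; ++i) {
          double u = pa[i] * c + pb[i] * s;
          double v = pb[i] * c - pa[i] * s;
          if (u < l1) l1 = u;
          if (u > h1) h1 = u;
          if (v < l2) l2 = v;
          if (v > h2) h2 = v;
        }
        double vol = wwidth * (h1 - l1) * (h2 - l2);
        if (vol < best) {
          best = vol;
          best_ang[0] = beta; best_ang[1] = gamma; best_ang[2] = alpha;
        }
      }
    }
  }
  return List::create(_["volume"] = best,
                      _["beta"] = best_ang[0], _["gamma"] = best_ang[1],
                      _["alpha"] = best_ang[2]);
}
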