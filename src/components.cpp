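#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D binary grid stored in R's
// column-major (Fortran) order. Labels are assigned in scan order of the
// first voxel encountered, so label 1 always holds the component whose
// minimum linear index is smallest.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  // neighbour offsets in (di, dj, dk)
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++cur;
    labels[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int m = 0; m < nn; ++m) {
        int i2 = i + di[m], j2 = j + dj[m], k2 = k + dk[m];
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
        R_xlen_t w = i2 + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2);
        if (mask[w] && !labels[w]) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = cur;
  return labels;
}
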