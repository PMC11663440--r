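#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a 2D/3D logical grid.
// dim = c(nx, ny, nz) with nz = 1 for 2D. connectivity: 6 (face) or 26
// (face+edge+corner); with nz = 1 these reduce to 4- and 8-connectivity.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) > 1)
              continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[nb] && !labels[nb]) {
              labels[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return labels;
}
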