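#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a binary grid under 6-, 18- or
// 26-neighbourhood connectivity. Labels are assigned in scan order and are
// therefore deterministic; relabeling by size happens at the R level.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector x, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("Array size does not match dims.");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan > 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!x[idx] || labels[idx] != 0) continue;
    ++next_label;
    labels[idx] = next_label;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx;
      int cx = rem % nx;
      for (size_t k = 0; k < dxs.size(); ++k) {
        int px = cx + dxs[k], py = cy + dys[k], pz = cz + dzs[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px;
        if (x[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
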