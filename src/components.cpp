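// 3-D connected-component labelling for cluster-extent inference.
// Flood fill over a logical volume with 6-, 18- or 26-neighbour
// connectivity; label order follows first-encountered linear index so
// results are deterministic.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector vol, IntegerVector dims,
                               int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != vol.size()) stop("dims do not match volume");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets at the requested connectivity
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        const int nonzero = (cx != 0) + (cy != 0) + (cz != 0);
        if (nonzero == 0) continue;
        if (connectivity == 6 && nonzero > 1) continue;
        if (connectivity == 18 && nonzero > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  IntegerVector labels(vol.size(), 0);
  std::vector<int> stack;
  int next_label = 0;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int lin = x + nx * (y + ny * z);
        if (!vol[lin] || labels[lin]) continue;
        ++next_label;
        labels[lin] = next_label;
        stack.clear();
        stack.push_back(lin);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (size_t k = 0; k < dx.size(); ++k) {
            const int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            const int plin = px + nx * (py + ny * pz);
            if (vol[plin] && !labels[plin]) {
              labels[plin] = next_label;
              stack.push_back(plin);
            }
          }
        }
      }

  labels.attr("dim") = dims;
  return labels;
}
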