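#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labelling on a flat logical array.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels, 0 = background, components numbered from 1
// in decreasing order of voxel count (label 1 is the largest).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<std::pair<R_xlen_t, int> > sizes; // (count, label)
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    R_xlen_t count = 0;
    stack.clear();
    stack.push_back(seed);
    labels[seed] = next_label;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      ++count;
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nidx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next_label;
          stack.push_back(nidx);
        }
      }
    }
    sizes.push_back(std::make_pair(count, next_label));
  }

  // relabel so that component 1 is the largest
  std::sort(sizes.begin(), sizes.end(),
            [](const std::pair<R_xlen_t, int>& a,
               const std::pair<R_xlen_t, int>& b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  std::vector<int> remap(next_label + 1, 0);
  for (size_t i = 0; i < sizes.size(); ++i)
    remap[sizes[i].second] = (int)(i + 1);
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] != 0) labels[i] = remap[labels[i]];

  IntegerVector ns((int)sizes.size());
  for (size_t i = 0; i < sizes.size(); ++i) ns[(int)i] = (int)sizes[i].first;
  labels.attr("component_sizes") = ns;
  return labels;
}
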