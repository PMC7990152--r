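#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first flood fill.
// connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are assigned in scan order of each component's first voxel, which
// makes the labeling deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)mask.size() != n) stop("mask/dim mismatch");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        off_x.push_back(dx);
        off_y.push_back(dy);
        off_z.push_back(dz);
      }
  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      const size_t cur = q.front();
      q.pop();
      const int z = (int)(cur / ((size_t)n1 * n2));
      const size_t rem = cur - (size_t)z * n1 * n2;
      const int y = (int)(rem / n1);
      const int x = (int)(rem % n1);
      for (size_t m = 0; m < off_x.size(); ++m) {
        const int nx = x + off_x[m], ny = y + off_y[m], nz = z + off_z[m];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= n1 || ny >= n2 || nz >= n3)
          continue;
        const size_t idx = (size_t)nz * n1 * n2 + (size_t)ny * n1 + nx;
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return labels;
}
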