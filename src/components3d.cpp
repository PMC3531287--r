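// 26-connected component labeling of a 3D logical mask (iterative flood fill).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((double)nx * ny * nz != (double)mask.size())
    stop("mask length does not match dims");
  IntegerVector labels(mask.size(), 0);
  int nextLabel = 0;
  std::vector<int> stack;
  const int nxy = nx * ny;
  for (int idx = 0; idx < (int)mask.size(); ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++nextLabel;
    stack.clear();
    stack.push_back(idx);
    labels[idx] = nextLabel;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / nxy;
      int rem = cur - z * nxy;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int nb = xx + nx * yy + nxy * zz;
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = nextLabel;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
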