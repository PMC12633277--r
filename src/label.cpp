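#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labelling of a logical matrix by breadth-first
// search.  connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Returns an integer matrix: 0 = background, components numbered from 1 in
// order of their first (row-major, top-left) pixel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nd = connectivity;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  // row-major scan so labels are ordered by top-left raster index
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * h);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % h, cc = idx / h;
        for (int k = 0; k < nd; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * h);
          }
        }
      }
    }
  }
  return lab;
}
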