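#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a logical mask by iterative flood fill.
// connectivity: 4 or 8. Labels are assigned in raster-scan order starting at 1;
// background stays 0. Deterministic for a given mask.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  // neighbour offsets (row, col)
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Count unordered 4-adjacent (white, black) pixel pairs.
// [[Rcpp::export(name = ".count_phase_boundaries_cpp")]]
int count_phase_boundaries_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  int n = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r + 1 < nr; ++r)
      if (mask(r, c) != mask(r + 1, c)) ++n;
  for (int c = 0; c + 1 < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) != mask(r, c + 1)) ++n;
  return n;
}
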