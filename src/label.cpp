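#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 2D binary image by breadth-first
// search. connectivity must be 4 or 8. Labels are assigned in raster-scan
// order of each component's first pixel, starting at 1; background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix img, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int qr = cr + dr8[k], qc = cc + dc8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (img(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}
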