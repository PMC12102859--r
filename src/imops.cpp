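#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary mask (non-zero = foreground).
// Returns an integer matrix of labels (0 = background, 1..k = components),
// with attribute "sizes" giving the pixel count of each component.
// [[Rcpp::export]]
IntegerMatrix label_components8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> sizes;
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      int count = 0;
      stack.push_back(r0 + nr * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % nr, c = p / nr;
        ++count;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
      sizes.push_back(count);
    }
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// Fill interior holes of a binary mask: background pixels not reachable
// from the image border by a 4-connected background path become foreground.
// [[Rcpp::export]]
IntegerMatrix fill_holes_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix reach(nr, nc);  // 1 = background reachable from border
  std::vector<int> stack;
  stack.reserve(256);
  auto push = [&](int r, int c) {
    if (mask(r, c) == 0 && reach(r, c) == 0) {
      reach(r, c) = 1;
      stack.push_back(r + nr * c);
    }
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p % nr, c = p / nr;
    if (r > 0)      push(r - 1, c);
    if (r < nr - 1) push(r + 1, c);
    if (c > 0)      push(r, c - 1);
    if (c < nc - 1) push(r, c + 1);
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = (mask(r, c) != 0 || reach(r, c) == 0) ? 1 : 0;
  return out;
}
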