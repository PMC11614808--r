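#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// two-pass union-find connected-component labeling on a binary mask;
// labels are consecutive 1..n in raster (row-major) order of first pixel
static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0);
  int next = 1;

  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously visited neighbours in raster order
      const int di4[2] = {-1, 0}, dj4[2] = {0, -1};
      const int di8[4] = {-1, -1, -1, 0}, dj8[4] = {-1, 0, 1, -1};
      int nn = (connectivity == 8) ? 4 : 2;
      const int* di = (connectivity == 8) ? di8 : di4;
      const int* dj = (connectivity == 8) ? dj8 : dj4;
      for (int k = 0; k < nn; ++k) {
        int ni = i + di[k], nj = j + dj[k];
        if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = best;
      }
    }
  }

  // second pass: resolve and relabel consecutively by raster order of roots
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (remap[r] == 0) remap[r] = ++out;
      lab(i, j) = remap[r];
    }
  return lab;
}
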