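#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label connected components of a binary mask
//'
//' Two-pass union-find labeling over a logical matrix. Foreground (TRUE)
//' pixels touching under the chosen connectivity receive the same positive
//' integer label; background pixels are 0. Labels are compacted to 1..k in
//' raster (column-major) order of first appearance.
//'
//' @param mask logical matrix
//' @param connectivity 4 (edge neighbors) or 8 (edge and corner neighbors)
//' @return integer matrix of the same dimensions
//' @keywords internal
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int m = mask.nrow(), n = mask.ncol();
  IntegerMatrix lab(m, n);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  // scan column-major; previously visited neighbors of (r, c):
  // (r-1, c) and, in column c-1, rows r (4-conn) plus r-1, r+1 (8-conn)
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < m; ++r) {
      if (!mask(r, c)) continue;
      int lbl = -1;
      if (r > 0 && mask(r - 1, c)) lbl = lab(r - 1, c) - 1;
      if (c > 0) {
        int lo = (connectivity == 8 && r > 0) ? r - 1 : r;
        int hi = (connectivity == 8 && r < m - 1) ? r + 1 : r;
        for (int rr = lo; rr <= hi; ++rr) {
          if (!mask(rr, c - 1)) continue;
          int other = lab(rr, c - 1) - 1;
          if (lbl == -1) lbl = other;
          else uf_union(parent, lbl, other);
        }
      }
      if (lbl == -1) {
        lbl = next++;
        parent.push_back(lbl);
      }
      lab(r, c) = lbl + 1;
    }
  }

  // second pass: resolve to roots, compact to 1..k
  std::vector<int> compact(next, 0);
  int k = 0;
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < m; ++r) {
      if (lab(r, c) == 0) continue;
      int root = uf_find(parent, lab(r, c) - 1);
      if (compact[root] == 0) compact[root] = ++k;
      lab(r, c) = compact[root];
    }
  }
  return lab;
}
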