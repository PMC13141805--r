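#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Two-pass connected-component labeling.
//'
//' Labels are assigned in scanline order of each component's first
//' (topmost, then leftmost) pixel, so the labeling is deterministic.
//' mask is a logical/integer matrix; connectivity is 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background
  int next = 1;

  // first pass: column-major storage but scan row-major (row = y, col = x)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int up   = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, ur = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        ur = (i > 0 && j < nc - 1 && mask(i - 1, j + 1)) ? lab(i - 1, j + 1) : 0;
      }
      int nb[4] = {up, left, ul, ur};
      int assigned = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (assigned == 0 || nb[k] < assigned)) assigned = nb[k];
      if (assigned == 0) {
        assigned = next++;
        parent.push_back(assigned);
      } else {
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) uf_union(parent, assigned, nb[k]);
      }
      lab(i, j) = assigned;
    }
  }

  // resolve equivalences, then relabel by order of first appearance in
  // row-major scan (topmost-leftmost pixel defines the component's rank)
  std::vector<int> remap(parent.size(), 0);
  int out = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!lab(i, j)) continue;
      int root = uf_find(parent, lab(i, j));
      if (remap[root] == 0) remap[root] = ++out;
      lab(i, j) = remap[root];
    }
  }
  return lab;
}
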