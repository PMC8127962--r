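#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Union-find with path compression.
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

//' 8-connected component labeling of a binary image
//'
//' Two-pass union-find labeling. Foreground pixels are those with a
//' nonzero value; labels are positive integers assigned in raster order
//' of each component's first pixel.
//'
//' @param mask logical/integer matrix; nonzero = foreground.
//' @return integer matrix of the same dimensions, 0 on background.
//' @keywords internal
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  // first pass: provisional labels, merging with the 4 already-seen
  // 8-neighbours (up-left, up, up-right in the same column sweep; we
  // sweep column-major to match R's layout: prev column is "left").
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      // neighbours already visited in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      const int nbr_r[4] = {r - 1, r - 1, r, r + 1};
      const int nbr_c[4] = {c, c - 1, c - 1, c - 1};
      for (int k = 0; k < 4; ++k) {
        int rr = nbr_r[k], cc = nbr_c[k];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best < 0) best = l - 1;
          else uf_union(parent, best, l - 1);
        }
      }
      if (best < 0) {
        parent.push_back(next);
        lab(r, c) = ++next;
      } else {
        lab(r, c) = uf_find(parent, best) + 1;
      }
    }
  }

  // second pass: flatten labels and renumber densely
  std::vector<int> remap(next, 0);
  int n_final = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l - 1);
      if (remap[root] == 0) remap[root] = ++n_final;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
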