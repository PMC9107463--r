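#include <Rcpp.h>
#include <vector>

// Two-pass union-find labelling of a binary mask, 8-connectivity.
// Returns an integer matrix: 0 for background, 1..k component ids
// (ids are compacted but otherwise arbitrary).

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".cc_label")]]
Rcpp::IntegerMatrix cc_label(Rcpp::LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // background sentinel

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int lbl = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int nl = lab(rr, cc);
        if (nl == 0) continue;
        if (lbl == 0) {
          lbl = find_root(parent, nl);
        } else {
          int other = find_root(parent, nl);
          if (other != lbl) {
            if (other < lbl) std::swap(other, lbl);
            parent[other] = lbl;
          }
        }
      }
      if (lbl == 0) {
        lbl = (int)parent.size();
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }

  // compact labels
  std::vector<int> remap(parent.size(), 0);
  int next_id = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (remap[root] == 0) remap[root] = ++next_id;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
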