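#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 8-connected component labeling with union-find.
// Returns an integer matrix: 0 = background, components numbered 1..K
// in first-encounter (column-major) order of their root pixels.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".cc_label_8")]]
IntegerMatrix cc_label_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;

  // first pass: scan column-major, look at already-visited 8-neighbors
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      // neighbors preceding (r,c) in column-major order:
      // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      const int dr[4] = {-1, -1, 0, 1};
      const int dc[4] = {0, -1, -1, -1};
      int neigh[4];
      int nn = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          neigh[nn++] = l - 1;
          if (best < 0 || l - 1 < best) best = l - 1;
        }
      }
      if (best < 0) {
        parent.push_back(next);
        lab(r, c) = ++next;
      } else {
        lab(r, c) = best + 1;
        for (int k = 0; k < nn; ++k) unite(parent, best, neigh[k]);
      }
    }
  }

  // relabel roots to consecutive ids
  std::vector<int> newid(parent.size(), 0);
  int K = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l - 1);
      if (newid[root] == 0) newid[root] = ++K;
      lab(r, c) = newid[root];
    }
  }
  lab.attr("n_components") = K;
  return lab;
}
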