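#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling.
// Scan order is raster (row by row, left to right); final labels are
// renumbered 1..R by the first-encountered pixel of each component so the
// labeling order is deterministic.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".ccl_label")]]
List ccl_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> provisional(nr * nc, 0);  // raster index -> provisional id
  std::vector<int> parent;
  parent.push_back(0);  // id 0 unused (background)

  // pass 1: raster scan, link to already-visited neighbours (N, W; +NW, NE)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int idx = r * nc + c;
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = provisional[idx - 1];
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = provisional[idx - nc];
      if (connectivity == 8 && r > 0) {
        if (c > 0 && mask(r - 1, c - 1)) neigh[nn++] = provisional[idx - nc - 1];
        if (c < nc - 1 && mask(r - 1, c + 1)) neigh[nn++] = provisional[idx - nc + 1];
      }
      for (int i = 0; i < nn; ++i)
        if (best == 0 || neigh[i] < best) best = neigh[i];
      if (best == 0) {
        best = (int) parent.size();
        parent.push_back(best);
      } else {
        for (int i = 0; i < nn; ++i) uf_union(parent, best, neigh[i]);
      }
      provisional[idx] = best;
    }
  }

  // pass 2: resolve roots, renumber by first occurrence in raster order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  std::vector<int> sizes;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int root = uf_find(parent, provisional[r * nc + c]);
      if (newlab[root] == 0) {
        newlab[root] = ++next;
        sizes.push_back(0);
      }
      int lab = newlab[root];
      labels(r, c) = lab;
      sizes[lab - 1]++;
    }
  }

  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
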