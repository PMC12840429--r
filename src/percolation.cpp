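#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Find with full path compression.
int uf_find(std::vector<int>& parent, int x) {
  int r = x;
  while (parent[r] != r) r = parent[r];
  while (parent[x] != r) {
    int nx = parent[x];
    parent[x] = r;
    x = nx;
  }
  return r;
}

} // namespace

//' @name label_clusters_cpp
//' @title Union-find cluster labeling of an occupancy grid (internal)
//' @description Labels 4-connected components of occupied sites. Empty sites
//'   get label 0; clusters get compact positive labels in column-major order
//'   of first appearance. Open (non-periodic) boundaries.
//' @param occ logical matrix of site occupancy
//' @return integer matrix of the same shape with cluster labels
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_clusters_cpp(const LogicalMatrix& occ) {
  const int nr = occ.nrow(), nc = occ.ncol(), n = nr * nc;
  std::vector<int> parent(n), sz(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int idx = i + j * nr;
      if (!occ[idx]) continue;
      if (i > 0 && occ[idx - 1]) {  // neighbor above
        int a = uf_find(parent, idx), b = uf_find(parent, idx - 1);
        if (a != b) {
          if (sz[a] < sz[b]) std::swap(a, b);
          parent[b] = a;
          sz[a] += sz[b];
        }
      }
      if (j > 0 && occ[idx - nr]) {  // neighbor to the left
        int a = uf_find(parent, idx), b = uf_find(parent, idx - nr);
        if (a != b) {
          if (sz[a] < sz[b]) std::swap(a, b);
          parent[b] = a;
          sz[a] += sz[b];
        }
      }
    }
  }

  IntegerMatrix labels(nr, nc);
  std::vector<int> compact(n, 0);
  int next_label = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!occ[idx]) {
      labels[idx] = 0;
      continue;
    }
    const int r = uf_find(parent, idx);
    if (compact[r] == 0) compact[r] = ++next_label;
    labels[idx] = compact[r];
  }
  return labels;
}

//' @name critical_index_cpp
//' @title Reverse union-find search for the critical removal index (internal)
//' @description Processes a removal trajectory backwards: starting from the
//'   never-removed (zero-probability) sites, trajectory sites are re-added in
//'   reverse removal order while clusters are merged incrementally and each
//'   root tracks which lattice edges its cluster touches. The first addition
//'   that creates a top-bottom or left-right spanning cluster identifies
//'   k*, the number of removals in the last spanning configuration.
//' @param order 1-based linear (column-major) site indices in removal order
//' @param excluded 1-based linear indices of sites never removed
//' @param nr,nc grid dimensions
//' @return k* as an integer, or -1 if the excluded sites alone span (the
//'   trajectory never breaks spanning)
//' @keywords internal
// [[Rcpp::export]]
int critical_index_cpp(const IntegerVector& order, const IntegerVector& excluded,
                       int nr, int nc) {
  const int n = nr * nc;
  std::vector<int> parent(n), sz(n, 1), mask(n, 0);
  std::vector<char> occ(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  bool spanning = false;

  // edge-contact bits: 1 top row, 2 bottom row, 4 left column, 8 right column
  auto add_site = [&](int idx) {
    occ[idx] = 1;
    const int i = idx % nr, j = idx / nr;
    int m = 0;
    if (i == 0) m |= 1;
    if (i == nr - 1) m |= 2;
    if (j == 0) m |= 4;
    if (j == nc - 1) m |= 8;
    mask[idx] = m;
    const int nb[4] = {i > 0 ? idx - 1 : -1, i < nr - 1 ? idx + 1 : -1,
                       j > 0 ? idx - nr : -1, j < nc - 1 ? idx + nr : -1};
    for (int t = 0; t < 4; ++t) {
      if (nb[t] < 0 || !occ[nb[t]]) continue;
      int a = uf_find(parent, idx), b = uf_find(parent, nb[t]);
      if (a == b) continue;
      if (sz[a] < sz[b]) std::swap(a, b);
      parent[b] = a;
      sz[a] += sz[b];
      mask[a] |= mask[b];
    }
    const int r = uf_find(parent, idx);
    const int mm = mask[r];
    if (((mm & 1) && (mm & 2)) || ((mm & 4) && (mm & 8))) spanning = true;
  };

  for (int t = 0; t < excluded.size(); ++t) add_site(excluded[t] - 1);
  if (spanning) return -1;

  for (int j = order.size() - 1; j >= 0; --j) {
    add_site(order[j] - 1);
    // config now equals "first j removals applied" (0-based j)
    if (spanning) return j;
  }
  return 0;  // full lattice always spans
}
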