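#include <Rcpp.h>
using namespace Rcpp;

// Union-find over pixel indices.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &rank_,
                     int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra == rb) return;
  if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
  parent[rb] = ra;
  if (rank_[ra] == rank_[rb]) rank_[ra]++;
}

//' Connected-component labeling of a categorical raster.
//'
//' Two-pass union-find labeling.  Pixels are connected when they are
//' neighbors under the requested connectivity, both inside the mask, and
//' carry the same category value.  Masked-out pixels get label NA.
//'
//' @param labels integer matrix of category codes
//' @param mask logical matrix, TRUE = valid pixel
//' @param connectivity 4 or 8
//' @return integer matrix of patch ids (1..n_patches), NA outside the mask
//' @keywords internal
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(IntegerMatrix labels, LogicalMatrix mask,
                       int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = labels.nrow(), nc = labels.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("mask dimensions must match labels");

  int n = nr * nc;
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // column-major index, matching R's matrix layout
  auto idx = [nr](int r, int c) { return c * nr + r; };

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int v = labels(r, c);
      // look back: left, up, and (8-conn) the two upper diagonals
      if (c > 0 && mask(r, c - 1) && labels(r, c - 1) == v)
        uf_union(parent, rank_, idx(r, c), idx(r, c - 1));
      if (r > 0 && mask(r - 1, c) && labels(r - 1, c) == v)
        uf_union(parent, rank_, idx(r, c), idx(r - 1, c));
      if (connectivity == 8 && r > 0) {
        if (c > 0 && mask(r - 1, c - 1) && labels(r - 1, c - 1) == v)
          uf_union(parent, rank_, idx(r, c), idx(r - 1, c - 1));
        if (c < nc - 1 && mask(r - 1, c + 1) && labels(r - 1, c + 1) == v)
          uf_union(parent, rank_, idx(r, c), idx(r - 1, c + 1));
      }
    }
  }

  IntegerMatrix out(nr, nc);
  std::vector<int> relabel(n, 0);
  int next_id = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) {
        out(r, c) = NA_INTEGER;
        continue;
      }
      int root = uf_find(parent, idx(r, c));
      if (relabel[root] == 0) relabel[root] = ++next_id;
      out(r, c) = relabel[root];
    }
  }
  return out;
}
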