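#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the top-two cluster-size statistic. Each draw samples
// k residues, links pairs closer than the threshold (distances computed on
// the fly from the residue centers, so no N x N matrix is ever built), and
// records the two largest connected-component sizes via union-find.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void top_two(const NumericMatrix &coords, const std::vector<int> &idx,
                    double thr2, int *t1, int *t2) {
  const int k = (int)idx.size();
  std::vector<int> parent(k), size(k, 1);
  for (int i = 0; i < k; ++i) parent[i] = i;
  for (int i = 0; i < k; ++i) {
    const double xi = coords(idx[i], 0), yi = coords(idx[i], 1),
                 zi = coords(idx[i], 2);
    for (int j = i + 1; j < k; ++j) {
      const double dx = xi - coords(idx[j], 0), dy = yi - coords(idx[j], 1),
                   dz = zi - coords(idx[j], 2);
      if (dx * dx + dy * dy + dz * dz < thr2) {
        int ri = uf_find(parent, i), rj = uf_find(parent, j);
        if (ri != rj) {
          if (size[ri] < size[rj]) std::swap(ri, rj);
          parent[rj] = ri;
          size[ri] += size[rj];
        }
      }
    }
  }
  int a = 0, b = 0;
  for (int i = 0; i < k; ++i) {
    if (parent[i] == i) {
      int s = size[i];
      if (s > a) { b = a; a = s; }
      else if (s > b) { b = s; }
    }
  }
  *t1 = a;
  *t2 = b;
}

// [[Rcpp::export]]
IntegerMatrix perm_top_two_kernel(NumericMatrix coords, double threshold,
                                  int k, int n_perm, bool replace) {
  const int n = coords.nrow();
  const double thr2 = threshold * threshold;
  IntegerMatrix out(n_perm, 2);
  std::vector<int> idx;
  idx.reserve(k);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector draw = sample(n, k, replace); // 1-based, R RNG
    idx.clear();
    if (replace) {
      std::vector<bool> seen(n, false);
      for (int i = 0; i < k; ++i) {
        int v = draw[i] - 1;
        if (!seen[v]) { seen[v] = true; idx.push_back(v); }
      }
    } else {
      for (int i = 0; i < k; ++i) idx.push_back(draw[i] - 1);
    }
    int t1, t2;
    top_two(coords, idx, thr2, &t1, &t2);
    out(p, 0) = t1;
    out(p, 1) = t2;
  }
  return out;
}
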