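#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &rank_, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) rank_[a]++;
}

// Connected components of the graph joining point pairs at Euclidean
// distance strictly below eps. Uses a uniform grid of cell size eps so only
// the 3x3 neighborhood of a point's grid cell is scanned; expected
// near-linear work for bounded local densities. Ties at exactly eps do not
// link. Returns 1-based component ids in order of first appearance.
// [[Rcpp::export]]
IntegerVector eps_components_cpp(NumericVector x, NumericVector y, double eps) {
  const int n = x.size();
  IntegerVector comp(n);
  if (n == 0) return comp;
  if (eps <= 0) {
    for (int i = 0; i < n; ++i) comp[i] = i + 1;
    return comp;
  }
  const double eps2 = eps * eps;
  std::unordered_map<std::int64_t, std::vector<int>> grid;
  grid.reserve(2 * n);
  std::vector<std::int64_t> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (std::int64_t)std::floor(x[i] / eps);
    gy[i] = (std::int64_t)std::floor(y[i] / eps);
    grid[(gx[i] << 32) ^ (gy[i] & 0xffffffffLL)].push_back(i);
  }
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    for (std::int64_t dx = -1; dx <= 1; ++dx) {
      for (std::int64_t dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(((gx[i] + dx) << 32) ^ ((gy[i] + dy) & 0xffffffffLL));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy < eps2)
            uf_union(parent, rank_, i, j);
        }
      }
    }
  }
  std::unordered_map<int, int> relabel;
  relabel.reserve(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      relabel[r] = ++next;
      comp[i] = next;
    } else {
      comp[i] = it->second;
    }
  }
  return comp;
}
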