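#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Cover times of simple random walks on a connected graph.
// adj: 0-based adjacency list. Each walk starts at a uniformly random
// vertex and hops to a uniformly random neighbour until every vertex has
// been visited; the returned value is the number of edge traversals.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cover_times_cpp(List adj, int walks) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
    if (nb[i].empty()) stop("graph must be connected (isolated vertex found)");
  }
  NumericVector out(walks);
  std::vector<char> seen(n);
  for (int w = 0; w < walks; ++w) {
    std::fill(seen.begin(), seen.end(), 0);
    int cur = (int)(unif_rand() * n);
    if (cur >= n) cur = n - 1;
    seen[cur] = 1;
    int visited = 1;
    double steps = 0.0;
    while (visited < n) {
      const std::vector<int>& cn = nb[cur];
      int k = (int)(unif_rand() * cn.size());
      if (k >= (int)cn.size()) k = cn.size() - 1;
      cur = cn[k];
      steps += 1.0;
      if (!seen[cur]) { seen[cur] = 1; ++visited; }
    }
    out[w] = steps;
  }
  return out;
}

// Exact minimum dominating set size by branch and bound over closed
// neighbourhoods (a set-cover search). Vertex sets are 64-bit masks, so
// n <= 64. Branches on an undominated vertex with the fewest dominators,
// prunes with the greedy upper bound and the counting lower bound
// ceil(undominated / max_coverage).
static int popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct DomCtx {
  int n;
  uint64_t full;
  std::vector<uint64_t> closed; // closed neighbourhood masks
  int best;
};

static void dom_search(DomCtx& C, uint64_t dominated, int size) {
  if (dominated == C.full) { if (size < C.best) C.best = size; return; }
  if (size + 1 >= C.best) return;
  uint64_t und = C.full & ~dominated;
  // lower bound: each added vertex dominates at most maxcov new vertices
  int maxcov = 0;
  for (int v = 0; v < C.n; ++v) {
    int c = popcnt(C.closed[v] & und);
    if (c > maxcov) maxcov = c;
  }
  int nund = popcnt(und);
  if (size + (nund + maxcov - 1) / maxcov >= C.best) return;
  // branch vertex: undominated vertex with fewest candidate dominators
  int bv = -1, bcnt = C.n + 1;
  for (int u = 0; u < C.n; ++u) {
    if (!((und >> u) & 1ULL)) continue;
    int cnt = 0;
    for (int v = 0; v < C.n; ++v)
      if ((C.closed[v] >> u) & 1ULL) ++cnt;
    if (cnt < bcnt) { bcnt = cnt; bv = u; }
  }
  // candidates = vertices whose closed neighbourhood contains bv,
  // tried in decreasing order of fresh coverage
  std::vector<std::pair<int, int>> cand;
  for (int v = 0; v < C.n; ++v)
    if ((C.closed[v] >> bv) & 1ULL)
      cand.push_back({-popcnt(C.closed[v] & und), v});
  std::sort(cand.begin(), cand.end());
  for (auto& pr : cand)
    dom_search(C, dominated | C.closed[pr.second], size + 1);
}

// [[Rcpp::export]]
int domination_number_cpp(LogicalMatrix adj) {
  int n = adj.nrow();
  if (n > 64) stop("exact domination solver supports n <= 64");
  DomCtx C;
  C.n = n;
  C.full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  C.closed.assign(n, 0);
  for (int v = 0; v < n; ++v) {
    C.closed[v] |= (1ULL << v);
    for (int u = 0; u < n; ++u)
      if (adj(v, u)) C.closed[v] |= (1ULL << u);
  }
  // greedy upper bound
  uint64_t dom = 0;
  int greedy = 0;
  while (dom != C.full) {
    int bv = -1, bc = -1;
    for (int v = 0; v < n; ++v) {
      int c = popcnt(C.closed[v] & ~dom);
      if (c > bc) { bc = c; bv = v; }
    }
    dom |= C.closed[bv];
    ++greedy;
  }
  C.best = greedy;
  dom_search(C, 0, 0);
  return C.best;
}
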