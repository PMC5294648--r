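#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disjoint-set sweep over the edges of a weighted graph in non-decreasing
// weight order (row-major tie order). Weight 1 is the non-edge sentinel and
// is never processed, so the filtration domain is [0, 1).
//
// bipartite = true : D is p x p over (X_i, Y_j) pairs; nodes 0..p-1 are the
//   X partition, p..2p-1 the Y partition, and every finite entry is an edge.
// bipartite = false: D is a symmetric p x p matrix over a single node set;
//   only the upper triangle (i < j) is swept.
//
// Returns, per merge event, the filtration value and the edge that caused the
// merge, plus the death values projected onto each partition, the
// single-linkage (first-connection / minimax) matrix over (X, Y) pairs and
// the projected ultrametrics within X and within Y.
// [[Rcpp::export(name = ".filt_core_cpp")]]
List filt_core_cpp(NumericMatrix D, bool bipartite) {
  const int p = D.nrow();
  if (D.ncol() != p) stop("distance matrix must be square");

  struct Edge { double w; int a; int b; };
  std::vector<Edge> edges;
  int n;
  if (bipartite) {
    n = 2 * p;
    edges.reserve(static_cast<size_t>(p) * p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (D(i, j) < 1.0) edges.push_back({D(i, j), i, p + j});
  } else {
    n = p;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (D(i, j) < 1.0) edges.push_back({D(i, j), i, j});
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) { return x.w < y.w; });

  std::vector<int> parent(n);
  // component member lists, split by partition (ym unused when !bipartite)
  std::vector<std::vector<int>> xm(n), ym(n);
  for (int v = 0; v < n; ++v) {
    parent[v] = v;
    if (v < p) xm[v].push_back(v); else ym[v].push_back(v - p);
  }

  NumericMatrix slm(p, p), ux(p, p), uy(p, p);
  std::fill(slm.begin(), slm.end(), 1.0);
  std::fill(ux.begin(), ux.end(), 1.0);
  std::fill(uy.begin(), uy.end(), 1.0);
  for (int i = 0; i < p; ++i) { ux(i, i) = 0.0; uy(i, i) = 0.0; }

  std::vector<double> ev_eps, deaths_x, deaths_y;
  std::vector<int> ev_a, ev_b;

  auto find = [&parent](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };

  for (const Edge& e : edges) {
    int ra = find(e.a), rb = find(e.b);
    if (ra == rb) continue;
    const double eps = e.w;
    ev_eps.push_back(eps);
    ev_a.push_back(e.a + 1);
    ev_b.push_back(e.b + 1);

    const std::vector<int>& xa = xm[ra]; const std::vector<int>& xb = xm[rb];
    const std::vector<int>& ya = ym[ra]; const std::vector<int>& yb = ym[rb];

    if (bipartite) {
      for (int x : xa) for (int y : yb) slm(x, y) = eps;
      for (int x : xb) for (int y : ya) slm(x, y) = eps;
      for (int y1 : ya) for (int y2 : yb) { uy(y1, y2) = eps; uy(y2, y1) = eps; }
      if (!ya.empty() && !yb.empty()) deaths_y.push_back(eps);
    }
    for (int x1 : xa) for (int x2 : xb) { ux(x1, x2) = eps; ux(x2, x1) = eps; }
    if (!xa.empty() && !xb.empty()) deaths_x.push_back(eps);

    // union by (total) size, append smaller member lists into larger
    int big = ra, small = rb;
    if (xm[ra].size() + ym[ra].size() < xm[rb].size() + ym[rb].size())
      std::swap(big, small);
    parent[small] = big;
    xm[big].insert(xm[big].end(), xm[small].begin(), xm[small].end());
    ym[big].insert(ym[big].end(), ym[small].begin(), ym[small].end());
    xm[small].clear(); xm[small].shrink_to_fit();
    ym[small].clear(); ym[small].shrink_to_fit();
  }

  List out = List::create(
    _["eps"] = ev_eps,
    _["node_a"] = ev_a,
    _["node_b"] = ev_b,
    _["deaths_x"] = deaths_x,
    _["ux"] = ux);
  if (bipartite) {
    out["deaths_y"] = deaths_y;
    out["slm"] = slm;
    out["uy"] = uy;
  }
  return out;
}
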