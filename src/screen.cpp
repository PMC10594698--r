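#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Greedy enumeration of low-weight directed paths from `source` to `target`
// on an edge list with non-negative weights. Mirrors the published loop:
//   1. find the minimum-weight source->target path (reverse Dijkstra from
//      the target plus a forward walk that, among edges achieving the
//      optimum, always steps to the neighbour with the smallest name rank,
//      which yields the lexicographically smallest minimum-weight path);
//   2. stop when no path remains or its weight sum l >= l_max;
//   3. a 2-edge path is not stored; its last edge is deleted;
//   4. a path of >= 3 edges is stored and its edges except the first and
//      last are deleted.
// Every iteration deletes at least one edge, so at most m iterations run.
// Node and edge indices are 0-based; `name_rank` maps node index to the
// rank of its name in lexicographic order.
// [[Rcpp::export]]
List screen_paths_cpp(int n_nodes, IntegerVector efrom, IntegerVector eto,
                      NumericVector ew, int source, int target, double l_max,
                      IntegerVector name_rank) {
  const int m = efrom.size();
  std::vector<char> active(m, 1);
  std::vector<std::vector<int> > adj(n_nodes), radj(n_nodes);
  for (int e = 0; e < m; ++e) {
    adj[efrom[e]].push_back(e);
    radj[eto[e]].push_back(e);
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<int> > paths;
  std::vector<double> lsums;
  std::vector<double> dist(n_nodes);
  typedef std::pair<double, int> P;

  for (int iter = 0; iter <= m; ++iter) {
    // reverse Dijkstra: dist[v] = min weight of an active path v -> target
    std::fill(dist.begin(), dist.end(), INF);
    dist[target] = 0.0;
    std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
    pq.push(P(0.0, target));
    while (!pq.empty()) {
      P top = pq.top();
      pq.pop();
      int v = top.second;
      if (top.first > dist[v]) continue;
      for (size_t k = 0; k < radj[v].size(); ++k) {
        int e = radj[v][k];
        if (!active[e]) continue;
        int u = efrom[e];
        double nd = ew[e] + dist[v];
        if (nd < dist[u]) {
          dist[u] = nd;
          pq.push(P(nd, u));
        }
      }
    }
    double l = dist[source];
    if (!(l < l_max)) break;  // no path (inf) or at/above the threshold

    // forward walk: lexicographically smallest optimal path
    std::vector<int> nodes;
    nodes.push_back(source);
    int u = source;
    bool ok = true;
    for (int guard = 0; u != target; ++guard) {
      if (guard > n_nodes) {
        ok = false;
        break;
      }
      int best = -1;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int e = adj[u][k];
        if (!active[e]) continue;
        int v = eto[e];
        if (ew[e] + dist[v] == dist[u]) {
          if (best < 0 || name_rank[v] < name_rank[best]) best = v;
        }
      }
      if (best < 0) {
        ok = false;
        break;
      }
      nodes.push_back(best);
      u = best;
    }
    if (!ok) break;

    int n_edges = (int)nodes.size() - 1;
    if (n_edges == 2) {
      // too short to contain a PPI edge: drop its last edge and retry
      int a = nodes[1], b = nodes[2];
      for (size_t k = 0; k < adj[a].size(); ++k) {
        int e = adj[a][k];
        if (active[e] && eto[e] == b) active[e] = 0;
      }
    } else {
      paths.push_back(nodes);
      lsums.push_back(l);
      for (int i = 1; i + 1 < n_edges; ++i) {
        int a = nodes[i], b = nodes[i + 1];
        for (size_t k = 0; k < adj[a].size(); ++k) {
          int e = adj[a][k];
          if (active[e] && eto[e] == b) active[e] = 0;
        }
      }
    }
  }

  List rpaths(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    rpaths[i] = IntegerVector(paths[i].begin(), paths[i].end());
  }
  return List::create(_["paths"] = rpaths, _["l"] = NumericVector(lsums.begin(), lsums.end()));
}
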