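// Shortest paths on subgraph edge lists (local integer vertex ids).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Multi-source Dijkstra with per-source starting offsets; also returns the
// parent vertex and, for single-source runs, the first-hop neighbour
// ("branch") through which each vertex is reached.
// [[Rcpp::export(name = ".dijkstra_cpp")]]
List dijkstra_cpp(int nv, IntegerVector ei, IntegerVector ej,
                  NumericVector w, IntegerVector sources,
                  NumericVector offsets) {
  std::vector<std::vector<std::pair<int, double> > > adj(nv + 1);
  int ne = ei.size();
  for (int k = 0; k < ne; ++k) {
    adj[ei[k]].push_back(std::make_pair(ej[k], w[k]));
    adj[ej[k]].push_back(std::make_pair(ei[k], w[k]));
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nv + 1, INF);
  std::vector<int> parent(nv + 1, 0), branch(nv + 1, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int v = sources[s];
    double d0 = offsets.size() ? offsets[s] : 0.0;
    if (d0 < dist[v]) {
      dist[v] = d0;
      branch[v] = v;
      pq.push(std::make_pair(d0, v));
    }
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v] + 1e-15) continue;
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int u = adj[v][k].first;
      double nd = dist[v] + adj[v][k].second;
      if (nd < dist[u] - 1e-15) {
        dist[u] = nd;
        parent[u] = v;
        branch[u] = (branch[v] == v && dist[v] == 0.0 && sources.size() == 1)
                        ? u
                        : branch[v];
        pq.push(std::make_pair(nd, u));
      }
    }
  }
  return List::create(_["dist"] = wrap(dist), _["parent"] = wrap(parent),
                      _["branch"] = wrap(branch));
}
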