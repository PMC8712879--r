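#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Multi-source Dijkstra on an undirected weighted graph.
//
// Nodes are 1-based (R convention). Edges are given as parallel vectors
// (from, to, w); each edge is traversed in both directions. Sources carry
// individual onset times, so the result is the first-arrival time field
// min_s (onset_s + d(s, x)) -- exactly the boundary-value structure of the
// Eikonal problem restricted to the edge graph.
//
// [[Rcpp::export]]
NumericVector dijkstra_first_arrival(int n_nodes,
                                     IntegerVector from,
                                     IntegerVector to,
                                     NumericVector w,
                                     IntegerVector src_nodes,
                                     NumericVector src_times) {
  const double INF = std::numeric_limits<double>::infinity();
  int m = from.size();
  if (to.size() != m || w.size() != m)
    stop("edge vectors must have equal length");
  if (src_nodes.size() != src_times.size())
    stop("source node and onset vectors must have equal length");

  // CSR adjacency (both directions)
  std::vector<int> deg(n_nodes + 1, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a < 1 || a > n_nodes || b < 1 || b > n_nodes)
      stop("edge endpoint out of range");
    if (!(w[e] >= 0)) stop("edge weights must be non-negative and finite");
    deg[a]++; deg[b]++;
  }
  std::vector<int> ptr(n_nodes + 2, 0);
  for (int i = 1; i <= n_nodes; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj(2 * (size_t)m);
  std::vector<double> adjw(2 * (size_t)m);
  std::vector<int> fill(n_nodes + 1, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    int pa = ptr[a] + fill[a]++;
    int pb = ptr[b] + fill[b]++;
    adj[pa] = b; adjw[pa] = w[e];
    adj[pb] = a; adjw[pb] = w[e];
  }

  std::vector<double> dist(n_nodes + 1, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < src_nodes.size(); ++s) {
    int v = src_nodes[s];
    if (v < 1 || v > n_nodes) stop("source node out of range");
    double t0 = src_times[s];
    if (t0 < dist[v]) { dist[v] = t0; pq.push(QE(t0, v)); }
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    for (int p = ptr[v]; p < ptr[v + 1]; ++p) {
      int u = adj[p];
      double nd = d + adjw[p];
      if (nd < dist[u]) { dist[u] = nd; pq.push(QE(nd, u)); }
    }
  }

  NumericVector out(n_nodes);
  for (int i = 1; i <= n_nodes; ++i) out[i - 1] = dist[i];
  return out;
}
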