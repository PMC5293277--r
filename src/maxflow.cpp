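#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Dinic max-flow / min-cut on a pixel lattice with terminal capacities.
// Nodes 0..n-1 are pixels, n = source, n+1 = sink. n-links are undirected
// (equal residual capacity both ways), t-links directed. Returns the
// source-side indicator (1 = foreground) of the minimum cut.

struct Dinic {
  int n;
  std::vector<int> to, nxt, head;
  std::vector<double> cap;
  std::vector<int> level, it;

  explicit Dinic(int n_) : n(n_), head(n_, -1), level(n_), it(n_) {}

  void add_arc(int u, int v, double c, double c_rev) {
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]); head[u] = to.size() - 1;
    to.push_back(u); cap.push_back(c_rev); nxt.push_back(head[v]); head[v] = to.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int &e = it[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > 0) { cap[e] -= d; cap[e ^ 1] += d; return d; }
      }
    }
    return 0.0;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      for (int i = 0; i < n; ++i) it[i] = head[i];
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
};

// [[Rcpp::export]]
IntegerVector lattice_mincut(int n_nodes, IntegerVector from, IntegerVector to,
                             NumericVector w, NumericVector cap_src,
                             NumericVector cap_snk) {
  int s = n_nodes, t = n_nodes + 1;
  Dinic d(n_nodes + 2);
  int m = from.size();
  for (int i = 0; i < m; ++i) d.add_arc(from[i], to[i], w[i], w[i]);
  for (int i = 0; i < n_nodes; ++i) {
    if (cap_src[i] > 0) d.add_arc(s, i, cap_src[i], 0.0);
    if (cap_snk[i] > 0) d.add_arc(i, t, cap_snk[i], 0.0);
  }
  d.run(s, t);
  // source side = reachable from source in the residual graph
  IntegerVector fg(n_nodes, 0);
  std::vector<char> vis(n_nodes + 2, 0);
  std::queue<int> q;
  vis[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = d.head[u]; e != -1; e = d.nxt[e]) {
      int v = d.to[e];
      if (d.cap[e] > 1e-12 && !vis[v]) { vis[v] = 1; q.push(v); }
    }
  }
  for (int i = 0; i < n_nodes; ++i) fg[i] = vis[i];
  return fg;
}
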