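#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// Unweighted directed betweenness (Brandes 2001).  `edges` is a 2-column
// matrix of 0-based (from, to) pairs; the graph must be simple.  Returns the
// unnormalized sum over ordered (s, t) pairs of geodesic fractions through
// each node.
// [[Rcpp::export]]
NumericVector bc_brandes_cpp(IntegerMatrix edges, int n) {
  std::vector< std::vector<int> > adj(n);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) adj[edges(e, 0)].push_back(edges(e, 1));

  NumericVector bc(n);
  std::vector<int> dist(n), queue(n), order;
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();

    int head = 0, tail = 0;
    dist[s] = 0; sigma[s] = 1.0; queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      order.push_back(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[tail++] = w; }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}

// All-pairs BFS geodesic lengths; -1 marks unreachable ordered pairs.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix edges, int n) {
  std::vector< std::vector<int> > adj(n);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) adj[edges(e, 0)].push_back(edges(e, 1));

  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> queue(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    D(s, s) = 0; queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (D(s, w) < 0) { D(s, w) = D(s, v) + 1; queue[tail++] = w; }
      }
    }
  }
  return D;
}

// Degree-preserving randomization of a simple digraph by directed double-edge
// swaps: pick edges (a,b),(c,d) and rewire to (a,d),(c,b) unless that would
// create a self-loop or a duplicate edge.  In- and out-degree sequences are
// preserved exactly by construction.  Uses R's RNG so seeding via set.seed()
// makes draws reproducible.
// [[Rcpp::export]]
IntegerMatrix swap_randomize_cpp(IntegerMatrix edges, int n, int n_attempts) {
  int m = edges.nrow();
  std::vector<int> from(m), to(m);
  std::set<long long> present;
  for (int e = 0; e < m; ++e) {
    from[e] = edges(e, 0);
    to[e]   = edges(e, 1);
    present.insert((long long)from[e] * n + to[e]);
  }
  if (m >= 2) {
    for (int it = 0; it < n_attempts; ++it) {
      int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
      int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
      if (a == d || c == b) continue;            // would create a self-loop
      long long k1 = (long long)a * n + d;
      long long k2 = (long long)c * n + b;
      if (present.count(k1) || present.count(k2)) continue;  // duplicate edge
      present.erase((long long)a * n + b);
      present.erase((long long)c * n + d);
      present.insert(k1);
      present.insert(k2);
      to[e1] = d;
      to[e2] = b;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = from[e]; out(e, 1) = to[e]; }
  return out;
}
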