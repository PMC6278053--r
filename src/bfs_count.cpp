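#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// CSR adjacency over n nodes; undirected edges are inserted both ways.
// head[v] .. head[v+1]-1 index into (nbr, eid).
struct Adj {
  std::vector<int> head, nbr, eid;
};

static Adj build_adj(int n, const IntegerVector& from, const IntegerVector& to,
                     bool directed) {
  int m = from.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    deg[from[e]]++;
    if (!directed) deg[to[e]]++;
  }
  Adj a;
  a.head.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) a.head[v + 1] = a.head[v] + deg[v];
  a.nbr.assign(a.head[n], 0);
  a.eid.assign(a.head[n], 0);
  std::vector<int> pos(a.head.begin(), a.head.end() - 1);
  for (int e = 0; e < m; ++e) {
    a.nbr[pos[from[e]]] = to[e];
    a.eid[pos[from[e]]++] = e;
    if (!directed) {
      a.nbr[pos[to[e]]] = from[e];
      a.eid[pos[to[e]]++] = e;
    }
  }
  return a;
}

// BFS shortest-path counting (sigma accumulation) from s over the edges
// flagged present; returns per-node geodesic counts (0 when unreachable).
static void bfs_sigma(const Adj& a, int n, int s,
                      const std::vector<char>& present,
                      std::vector<double>& sigma, std::vector<int>& dist) {
  sigma.assign(n, 0.0);
  dist.assign(n, -1);
  std::queue<int> q;
  dist[s] = 0;
  sigma[s] = 1.0;
  q.push(s);
  while (!q.empty()) {
    int u = q.front();
    q.pop();
    for (int k = a.head[u]; k < a.head[u + 1]; ++k) {
      if (!present[a.eid[k]]) continue;
      int w = a.nbr[k];
      if (dist[w] < 0) {
        dist[w] = dist[u] + 1;
        sigma[w] = sigma[u];
        q.push(w);
      } else if (dist[w] == dist[u] + 1) {
        sigma[w] += sigma[u];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sp_count(int n, IntegerVector from, IntegerVector to,
                           bool directed, int source) {
  Adj a = build_adj(n, from, to, directed);
  std::vector<char> present(from.size(), 1);
  std::vector<double> sigma;
  std::vector<int> dist;
  bfs_sigma(a, n, source, present, sigma, dist);
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = (dist[v] < 0) ? 0.0 : sigma[v];
  out[source] = 0.0;
  return out;
}

// Mean geodesic counts from each source to every node over n_samples
// Bernoulli-sampled instances (edge e kept with probability p[e]).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_sampling_counts(int n, IntegerVector from, IntegerVector to,
                                  NumericVector p, bool directed,
                                  IntegerVector sources, int n_samples) {
  Adj a = build_adj(n, from, to, directed);
  int m = from.size(), ns = sources.size();
  NumericMatrix acc(ns, n);
  std::vector<char> present(m, 1);
  std::vector<double> sigma;
  std::vector<int> dist;
  RNGScope scope;
  for (int it = 0; it < n_samples; ++it) {
    for (int e = 0; e < m; ++e) present[e] = (unif_rand() < p[e]) ? 1 : 0;
    for (int si = 0; si < ns; ++si) {
      bfs_sigma(a, n, sources[si], present, sigma, dist);
      for (int v = 0; v < n; ++v)
        if (dist[v] > 0) acc(si, v) += sigma[v];
    }
  }
  for (int si = 0; si < ns; ++si)
    for (int v = 0; v < n; ++v) acc(si, v) /= n_samples;
  return acc;
}
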