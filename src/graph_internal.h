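#ifndef EVOMOTIF_GRAPH_INTERNAL_H
#define EVOMOTIF_GRAPH_INTERNAL_H

#include <Rcpp.h>
#include <vector>

// Mutable simple undirected graph on 0-based contiguous node ids.
// Adjacency is kept both as lists (iteration) and as a byte matrix
// (O(1) membership); the byte matrix caps N, ample for the population
// sizes the annealers are meant for.
struct MutGraph {
  int N;
  int E;
  std::vector<std::vector<int>> adj;
  std::vector<unsigned char> mat;
  std::vector<int> eu, ev;  // edge endpoint arrays, length E

  MutGraph(const Rcpp::IntegerMatrix& edges, int n) : N(n) {
    if (n > 4096) Rcpp::stop("internal graph engine supports N <= 4096");
    E = edges.nrow();
    adj.assign(N, {});
    mat.assign((size_t)N * N, 0);
    eu.resize(E);
    ev.resize(E);
    for (int e = 0; e < E; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      if (a < 0 || b < 0 || a >= N || b >= N) Rcpp::stop("node id out of range");
      if (a == b) Rcpp::stop("self-loop in edge list");
      if (has(a, b)) Rcpp::stop("parallel edge in edge list");
      eu[e] = a;
      ev[e] = b;
      link(a, b);
    }
  }

  bool has(int a, int b) const { return mat[(size_t)a * N + b] != 0; }

  void link(int a, int b) {
    mat[(size_t)a * N + b] = mat[(size_t)b * N + a] = 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }

  void unlink(int a, int b) {
    mat[(size_t)a * N + b] = mat[(size_t)b * N + a] = 0;
    drop(adj[a], b);
    drop(adj[b], a);
  }

  static void drop(std::vector<int>& v, int x) {
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == x) {
        v[i] = v.back();
        v.pop_back();
        return;
      }
  }

  // common neighbours of a and b = triangles through edge (a,b) when adjacent
  int common(int a, int b) const {
    bool a_small = adj[a].size() <= adj[b].size();
    const std::vector<int>& sm = a_small ? adj[a] : adj[b];
    int other = a_small ? b : a;
    int c = 0;
    for (int z : sm) c += has(other, z);
    return c;
  }

  long long triangles() const {
    long long t = 0;
    for (int e = 0; e < E; ++e) t += common(eu[e], ev[e]);
    return t / 3;
  }

  // open+closed triple (wedge) count: sum over nodes of k(k-1)/2;
  // invariant under degree-preserving swaps
  long long wedges() const {
    long long w = 0;
    for (int v = 0; v < N; ++v) {
      long long k = (long long)adj[v].size();
      w += k * (k - 1) / 2;
    }
    return w;
  }

  bool connected(std::vector<int>& stack, std::vector<unsigned char>& seen) const {
    if (N == 0) return true;
    seen.assign(N, 0);
    stack.clear();
    stack.push_back(0);
    seen[0] = 1;
    int reached = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int w : adj[v])
        if (!seen[w]) {
          seen[w] = 1;
          ++reached;
          stack.push_back(w);
        }
    }
    return reached == N;
  }
};

inline Rcpp::IntegerMatrix canonical_edges(const std::vector<int>& eu,
                                           const std::vector<int>& ev) {
  int E = (int)eu.size();
  Rcpp::IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = eu[e] < ev[e] ? eu[e] : ev[e];
    out(e, 1) = eu[e] < ev[e] ? ev[e] : eu[e];
  }
  return out;
}

inline int rnd_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

#endif
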