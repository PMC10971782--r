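#include "graph_internal.h"
#include <map>
using namespace Rcpp;

// Metropolis-Hastings annealer on the triangle fraction phi for graphs with a
// fixed degree sequence (double edge swaps). Acceptance uses the ratio of
// Gaussian densities centred at phi_target with growing width sigma; moves
// toward the target are always accepted. Invalid proposals (self-loop /
// multi-edge) are re-drawn without consuming budget; accepted swaps that
// disconnect the graph are reverted. Returns the best-visited state.
// [[Rcpp::export]]
List cpp_tune_phi(IntegerMatrix edges, int N, double phi_target, double sigma0,
                  double sigma_growth, long long sigma_interval,
                  long long budget, double stop_tol, long long trace_interval) {
  MutGraph g(edges, N);
  long long W = g.wedges();
  if (W == 0) stop("graph has no wedges; transitivity undefined");
  long long T = g.triangles();
  double phi = 3.0 * (double)T / (double)W;

  std::vector<int> best_eu = g.eu, best_ev = g.ev;
  double best_diff = std::fabs(phi - phi_target), best_phi = phi;
  double sigma = sigma0;
  long long proposals = 0, accepted = 0;
  int stall = 0;
  bool stalled = false;
  std::vector<int> stack;
  std::vector<unsigned char> seen;
  std::vector<double> trace;

  while (proposals < budget) {
    if (stop_tol >= 0 && best_diff <= stop_tol) break;
    int i1 = rnd_int(g.E), i2 = rnd_int(g.E);
    int a = g.eu[i1], b = g.ev[i1], c = g.eu[i2], d = g.ev[i2];
    if (unif_rand() < 0.5) std::swap(c, d);
    bool valid = a != c && a != d && b != c && b != d && !g.has(a, c) && !g.has(b, d);
    if (!valid) {
      if (++stall > 200000) { stalled = true; break; }
      continue;
    }
    stall = 0;
    ++proposals;
    if ((proposals & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    long long dT = 0;
    dT -= g.common(a, b); g.unlink(a, b);
    dT -= g.common(c, d); g.unlink(c, d);
    dT += g.common(a, c); g.link(a, c);
    dT += g.common(b, d); g.link(b, d);
    double phi2 = 3.0 * (double)(T + dT) / (double)W;

    double d0 = std::fabs(phi - phi_target), d1 = std::fabs(phi2 - phi_target);
    bool acc = d1 <= d0 ||
               unif_rand() < std::exp((d0 * d0 - d1 * d1) / (2.0 * sigma * sigma));
    if (acc && !g.connected(stack, seen)) acc = false;
    if (acc) {
      g.eu[i1] = a; g.ev[i1] = c;
      g.eu[i2] = b; g.ev[i2] = d;
      T += dT;
      phi = phi2;
      ++accepted;
      if (d1 < best_diff) {
        best_diff = d1; best_phi = phi;
        best_eu = g.eu; best_ev = g.ev;
      }
    } else {
      g.unlink(b, d); g.unlink(a, c);
      g.link(c, d); g.link(a, b);
    }
    if (sigma_interval > 0 && proposals % sigma_interval == 0) sigma *= sigma_growth;
    if (trace_interval > 0 && proposals % trace_interval == 0) trace.push_back(phi);
  }

  return List::create(
      _["edges"] = canonical_edges(best_eu, best_ev), _["phi"] = best_phi,
      _["phi_final"] = phi, _["proposals"] = (double)proposals,
      _["accepted"] = (double)accepted, _["sigma_final"] = sigma,
      _["stalled"] = stalled, _["trace"] = trace);
}

// Annealer on degree assortativity r via double edge swaps. Degrees are
// invariant under the swap, so r changes only through the sum of
// degree products over edges; the update is O(1).
// [[Rcpp::export]]
List cpp_tune_assort(IntegerMatrix edges, int N, double r_target, double sigma0,
                     double sigma_growth, long long sigma_interval,
                     long long budget, double stop_tol) {
  MutGraph g(edges, N);
  std::vector<double> deg(N);
  for (int v = 0; v < N; ++v) deg[v] = (double)g.adj[v].size();
  double S = 0, sumd = 0, sumd2 = 0;
  for (int e = 0; e < g.E; ++e) {
    double du = deg[g.eu[e]], dv = deg[g.ev[e]];
    S += du * dv;
    sumd += du + dv;
    sumd2 += du * du + dv * dv;
  }
  double twoE = 2.0 * g.E;
  double mu = sumd / twoE;
  double den = sumd2 / twoE - mu * mu;
  if (den <= 0) stop("assortativity undefined for regular graphs");
  auto rval = [&](double Ssum) { return (Ssum / g.E - mu * mu) / den; };
  double r = rval(S);

  std::vector<int> best_eu = g.eu, best_ev = g.ev;
  double best_diff = std::fabs(r - r_target), best_r = r;
  double sigma = sigma0;
  long long proposals = 0, accepted = 0;
  int stall = 0;
  bool stalled = false;
  std::vector<int> stack;
  std::vector<unsigned char> seen;

  while (proposals < budget) {
    if (stop_tol >= 0 && best_diff <= stop_tol) break;
    int i1 = rnd_int(g.E), i2 = rnd_int(g.E);
    int a = g.eu[i1], b = g.ev[i1], c = g.eu[i2], d = g.ev[i2];
    if (unif_rand() < 0.5) std::swap(c, d);
    bool valid = a != c && a != d && b != c && b != d && !g.has(a, c) && !g.has(b, d);
    if (!valid) {
      if (++stall > 200000) { stalled = true; break; }
      continue;
    }
    stall = 0;
    ++proposals;
    if ((proposals & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    double dS = deg[a] * deg[c] + deg[b] * deg[d] - deg[a] * deg[b] - deg[c] * deg[d];
    double r2 = rval(S + dS);
    double d0 = std::fabs(r - r_target), d1 = std::fabs(r2 - r_target);
    bool acc = d1 <= d0 ||
               unif_rand() < std::exp((d0 * d0 - d1 * d1) / (2.0 * sigma * sigma));
    if (acc) {
      g.unlink(a, b); g.unlink(c, d);
      g.link(a, c); g.link(b, d);
      if (!g.connected(stack, seen)) {
        g.unlink(a, c); g.unlink(b, d);
        g.link(a, b); g.link(c, d);
        acc = false;
      }
    }
    if (acc) {
      g.eu[i1] = a; g.ev[i1] = c;
      g.eu[i2] = b; g.ev[i2] = d;
      S += dS;
      r = r2;
      ++accepted;
      if (d1 < best_diff) {
        best_diff = d1; best_r = r;
        best_eu = g.eu; best_ev = g.ev;
      }
    }
    if (sigma_interval > 0 && proposals % sigma_interval == 0) sigma *= sigma_growth;
  }

  return List::create(
      _["edges"] = canonical_edges(best_eu, best_ev), _["r"] = best_r,
      _["r_final"] = r, _["proposals"] = (double)proposals,
      _["accepted"] = (double)accepted, _["stalled"] = stalled);
}

// 2K-preserving annealer on phi: swaps act on pairs of edges of the same
// type (same unordered degree pair), aligning like-degree endpoints, so the
// joint degree matrix (hence degree distribution and assortativity) is
// conserved exactly. Toward-target moves are always accepted; away moves
// with probability gamma, which decays on a schedule.
// [[Rcpp::export]]
List cpp_tune_phi_2k(IntegerMatrix edges, int N, double phi_target, double gamma0,
                     double gamma_decay, long long gamma_interval,
                     long long budget, double stop_tol) {
  MutGraph g(edges, N);
  long long W = g.wedges();
  if (W == 0) stop("graph has no wedges; transitivity undefined");

  // orient each stored edge high-degree end first; class edges by degree pair
  std::vector<int> deg(N);
  for (int v = 0; v < N; ++v) deg[v] = (int)g.adj[v].size();
  std::map<std::pair<int, int>, int> class_id;
  std::vector<std::vector<int>> class_edges;
  std::vector<int> etype(g.E);
  for (int e = 0; e < g.E; ++e) {
    if (deg[g.eu[e]] < deg[g.ev[e]]) std::swap(g.eu[e], g.ev[e]);
    std::pair<int, int> key(deg[g.eu[e]], deg[g.ev[e]]);
    auto it = class_id.find(key);
    int id;
    if (it == class_id.end()) {
      id = (int)class_edges.size();
      class_id[key] = id;
      class_edges.push_back({});
    } else {
      id = it->second;
    }
    etype[e] = id;
    class_edges[id].push_back(e);
  }
  bool feasible = false;
  for (auto& ce : class_edges) feasible = feasible || ce.size() >= 2;
  if (!feasible) stop("2K swap infeasible: no two edges share a type");

  long long T = g.triangles();
  double phi = 3.0 * (double)T / (double)W;
  std::vector<int> best_eu = g.eu, best_ev = g.ev;
  double best_diff = std::fabs(phi - phi_target), best_phi = phi;
  double gamma = gamma0;
  long long proposals = 0, accepted = 0;
  int stall = 0;
  bool stalled = false;
  std::vector<int> stack;
  std::vector<unsigned char> seen;

  while (proposals < budget) {
    if (stop_tol >= 0 && best_diff <= stop_tol) break;
    int i1 = rnd_int(g.E);
    const std::vector<int>& cls = class_edges[etype[i1]];
    int i2 = cls[rnd_int((int)cls.size())];
    bool bad = i2 == i1;
    int a = g.eu[i1], b = g.ev[i1], c = 0, d = 0;
    if (!bad) {
      c = g.eu[i2]; d = g.ev[i2];
      bool same_deg = deg[a] == deg[b];
      if (same_deg && unif_rand() < 0.5) std::swap(c, d);
      bad = a == c || a == d || b == c || b == d || g.has(a, d) || g.has(c, b);
    }
    if (bad) {
      if (++stall > 200000) { stalled = true; break; }
      continue;
    }
    stall = 0;
    ++proposals;
    if ((proposals & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    // new edges (a,d) and (c,b): degree pairs identical to the old ones
    long long dT = 0;
    dT -= g.common(a, b); g.unlink(a, b);
    dT -= g.common(c, d); g.unlink(c, d);
    dT += g.common(a, d); g.link(a, d);
    dT += g.common(c, b); g.link(c, b);
    double phi2 = 3.0 * (double)(T + dT) / (double)W;

    double d0 = std::fabs(phi - phi_target), d1 = std::fabs(phi2 - phi_target);
    bool acc = d1 <= d0 || unif_rand() < gamma;
    if (acc && !g.connected(stack, seen)) acc = false;
    if (acc) {
      g.eu[i1] = a; g.ev[i1] = d;
      g.eu[i2] = c; g.ev[i2] = b;
      T += dT;
      phi = phi2;
      ++accepted;
      if (d1 < best_diff) {
        best_diff = d1; best_phi = phi;
        best_eu = g.eu; best_ev = g.ev;
      }
    } else {
      g.unlink(c, b); g.unlink(a, d);
      g.link(c, d); g.link(a, b);
    }
    if (gamma_interval > 0 && proposals % gamma_interval == 0) gamma *= gamma_decay;
  }

  return List::create(
      _["edges"] = canonical_edges(best_eu, best_ev), _["phi"] = best_phi,
      _["phi_final"] = phi, _["proposals"] = (double)proposals,
      _["accepted"] = (double)accepted, _["gamma_final"] = gamma,
      _["stalled"] = stalled);
}
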