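#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rank-selection Birth-death optimizer on a population graph. Each event:
// a reproducer is drawn fitness-proportionally over the whole population,
// with fitness a linear function of objective-value rank from (1+s) down to
// (1-s); a uniformly random neighbour is replaced by a copy of the
// reproducer; then either the parent or the offspring (fair coin) mutates by
// adding Gaussian noise to its genotype. The population mean objective value
// is recorded every `cadence` events.
namespace {

inline double objective_value(int id, const double* x, int dim, const double* opt) {
  if (id == 0) {  // concave quadratic, maximum 1 at opt
    double ss = 0;
    for (int c = 0; c < dim; ++c) {
      double d = x[c] - opt[c];
      ss += d * d;
    }
    return 1.0 - ss;
  }
  // inverted Rastrigin (A = 10), maximum 0 at the origin
  double v = 10.0 * dim;
  for (int c = 0; c < dim; ++c)
    v += x[c] * x[c] - 10.0 * std::cos(2.0 * M_PI * x[c]);
  return -v;
}

}  // namespace

// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix edges, int N, int objective, int dim,
                NumericVector start, NumericVector optimum, double s,
                double mutation_sd, double theta, double cadence,
                double max_events, int nrep, bool record_traj,
                bool stop_at_threshold) {
  long long E = edges.nrow();
  std::vector<int> deg(N, 0), off(N + 1, 0);
  for (long long e = 0; e < E; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  for (int v = 0; v < N; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> nb(2 * E), cur(off.begin(), off.end() - 1);
  for (long long e = 0; e < E; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    nb[cur[a]++] = b;
    nb[cur[b]++] = a;
  }

  // rank weights: rank j (best = 0) has fitness (1+s) - 2 s j/(N-1);
  // cumulative sums give O(log N) fitness-proportional rank sampling
  std::vector<double> cumw(N);
  double acc = 0;
  for (int j = 0; j < N; ++j) {
    acc += (1.0 + s) - 2.0 * s * j / (N - 1.0);
    cumw[j] = acc;
  }

  int ncheck = (int)(max_events / cadence);
  NumericMatrix traj(record_traj ? ncheck : 0, record_traj ? nrep : 0);
  NumericVector times(nrep, NA_REAL);

  std::vector<double> G((size_t)N * dim), vals(N);
  std::vector<int> ord(N), pos(N);

  for (int rep = 0; rep < nrep; ++rep) {
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < dim; ++c) G[(size_t)i * dim + c] = start[c];
    double v0 = objective_value(objective, &G[0], dim, optimum.begin());
    std::fill(vals.begin(), vals.end(), v0);
    double vsum = v0 * N;
    for (int i = 0; i < N; ++i) { ord[i] = i; pos[i] = i; }

    auto resort = [&](int idx) {
      // bubble idx to its place in the descending order
      int p = pos[idx];
      while (p > 0 && vals[ord[p - 1]] < vals[idx]) {
        ord[p] = ord[p - 1];
        pos[ord[p]] = p;
        --p;
      }
      while (p < N - 1 && vals[ord[p + 1]] > vals[idx]) {
        ord[p] = ord[p + 1];
        pos[ord[p]] = p;
        ++p;
      }
      ord[p] = idx;
      pos[idx] = p;
    };

    if (!ISNA(theta) && vsum / N >= theta) {
      // already at target before any event
      times[rep] = 0;
      if (record_traj)
        for (int c2 = 0; c2 < ncheck; ++c2) traj(c2, rep) = vsum / N;
      continue;
    }

    double t = 0, next_rec = cadence;
    int chk = 0;
    while (t < max_events) {
      double u = unif_rand() * cumw[N - 1];
      int j = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      if (j >= N) j = N - 1;
      int parent = ord[j];
      int k = off[parent + 1] - off[parent];
      int victim = nb[off[parent] + (int)(unif_rand() * k)];
      for (int c = 0; c < dim; ++c)
        G[(size_t)victim * dim + c] = G[(size_t)parent * dim + c];
      int mut_target = unif_rand() < 0.5 ? parent : victim;
      for (int c = 0; c < dim; ++c)
        G[(size_t)mut_target * dim + c] += norm_rand() * mutation_sd;

      double nv = objective_value(objective, &G[(size_t)victim * dim], dim,
                                  optimum.begin());
      vsum += nv - vals[victim];
      vals[victim] = nv;
      resort(victim);
      if (mut_target == parent) {
        nv = objective_value(objective, &G[(size_t)parent * dim], dim,
                             optimum.begin());
        vsum += nv - vals[parent];
        vals[parent] = nv;
        resort(parent);
      }
      t += 1;
      if (t >= next_rec) {
        double meanv = vsum / N;
        if (record_traj && chk < ncheck) traj(chk, rep) = meanv;
        ++chk;
        next_rec += cadence;
        if (!ISNA(theta) && ISNA(times[rep]) && meanv >= theta) {
          times[rep] = t;
          if (stop_at_threshold) break;
        }
      }
    }
    // carry the final mean forward for replicates that finished early
    if (record_traj && chk > 0)
      for (; chk < ncheck; ++chk) traj(chk, rep) = traj(chk - 1, rep);
    Rcpp::checkUserInterrupt();
  }

  NumericVector taxis(record_traj ? ncheck : 0);
  for (int i = 0; i < (int)taxis.size(); ++i) taxis[i] = cadence * (i + 1);
  return List::create(_["times"] = times, _["traj"] = traj, _["time_axis"] = taxis);
}
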