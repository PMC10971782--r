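#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Moran Birth-death / death-Birth engine. Population state is a 0/1 type
// vector (1 = mutant, fitness 1+s); the mixed (Aa) edge count is maintained
// incrementally in O(degree) per event. Time is counted in elementary Moran
// events (one replacement attempt); a generation is N events.
namespace {

struct Moran {
  int N;
  long long E;
  std::vector<int> off, nb;  // CSR adjacency
  std::vector<unsigned char> type;
  std::vector<int> mut, wt, pos;  // member lists and positions within them
  int m;
  long long mixed;  // count of edges whose endpoints differ in type
  long long sdeg;   // sum of degrees over mutant nodes

  Moran(const IntegerMatrix& edges, int n) : N(n) {
    E = edges.nrow();
    std::vector<int> deg(N, 0);
    for (long long e = 0; e < E; ++e) {
      ++deg[edges(e, 0)];
      ++deg[edges(e, 1)];
    }
    off.assign(N + 1, 0);
    for (int v = 0; v < N; ++v) off[v + 1] = off[v] + deg[v];
    nb.resize(2 * E);
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (long long e = 0; e < E; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      nb[cur[a]++] = b;
      nb[cur[b]++] = a;
    }
    type.resize(N);
    pos.resize(N);
  }

  void reset(const std::vector<int>& mutants) {
    std::fill(type.begin(), type.end(), 0);
    for (int v : mutants) type[v] = 1;
    mut.clear();
    wt.clear();
    for (int v = 0; v < N; ++v) {
      if (type[v]) {
        pos[v] = (int)mut.size();
        mut.push_back(v);
      } else {
        pos[v] = (int)wt.size();
        wt.push_back(v);
      }
    }
    m = (int)mut.size();
    mixed = recount_mixed();
    sdeg = 0;
    for (int v : mut) sdeg += off[v + 1] - off[v];
  }

  long long recount_mixed() const {
    long long mx = 0;
    for (int v = 0; v < N; ++v)
      if (type[v])
        for (int i = off[v]; i < off[v + 1]; ++i) mx += type[nb[i]] == 0;
    return mx;
  }

  int rnd(int n) const {
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
  }

  void flip(int v) {
    // update mixed-edge count before flipping
    long long same = 0, diff = 0;
    for (int i = off[v]; i < off[v + 1]; ++i) {
      if (type[nb[i]] == type[v]) ++same; else ++diff;
    }
    mixed += same - diff;
    if (type[v]) {
      // mutant -> wild
      int p = pos[v], last = mut.back();
      mut[p] = last;
      pos[last] = p;
      mut.pop_back();
      pos[v] = (int)wt.size();
      wt.push_back(v);
      type[v] = 0;
      --m;
    } else {
      int p = pos[v], last = wt.back();
      wt[p] = last;
      pos[last] = p;
      wt.pop_back();
      pos[v] = (int)mut.size();
      mut.push_back(v);
      type[v] = 1;
      ++m;
    }
    int dv = off[v + 1] - off[v];
    sdeg += type[v] ? dv : -dv;
  }

  // one Bd event: reproducer fitness-proportional, victim uniform neighbour
  void step_bd(double s) {
    double wtot = N + s * m;
    int rep;
    if (unif_rand() * wtot < (1.0 + s) * m)
      rep = mut[rnd(m)];
    else
      rep = wt[rnd(N - m)];
    int k = off[rep + 1] - off[rep];
    int victim = nb[off[rep] + rnd(k)];
    if (type[victim] != type[rep]) flip(victim);
  }

  // one dB event: victim uniform over nodes, parent fitness-proportional
  // among the victim's neighbours
  void step_db(double s) {
    int victim = rnd(N);
    int lo = off[victim], hi = off[victim + 1];
    double wsum = 0;
    for (int i = lo; i < hi; ++i) wsum += type[nb[i]] ? 1.0 + s : 1.0;
    double u = unif_rand() * wsum;
    int parent = nb[hi - 1];
    for (int i = lo; i < hi; ++i) {
      u -= type[nb[i]] ? 1.0 + s : 1.0;
      if (u <= 0) { parent = nb[i]; break; }
    }
    if (type[victim] != type[parent]) flip(victim);
  }

  std::vector<int> draw_init(const std::vector<int>& init_nodes, int init_count) {
    if (!init_nodes.empty()) return init_nodes;
    std::vector<int> res;
    std::vector<unsigned char> used(N, 0);
    while ((int)res.size() < init_count) {
      int v = rnd(N);
      if (!used[v]) {
        used[v] = 1;
        res.push_back(v);
      }
    }
    return res;
  }
};

}  // namespace

// Ensemble of independent runs to absorption; returns per-run fixation /
// loss times (in events) and the censored count.
// [[Rcpp::export]]
List cpp_moran_ensemble(IntegerMatrix edges, int N, double s, int rule, int nrep,
                        double cap, IntegerVector init_nodes, int init_count) {
  Moran mo(edges, N);
  std::vector<int> init(init_nodes.begin(), init_nodes.end());
  std::vector<double> fix_times, loss_times;
  int censored = 0;
  for (int r = 0; r < nrep; ++r) {
    mo.reset(mo.draw_init(init, init_count));
    double t = 0;
    while (mo.m > 0 && mo.m < N && t < cap) {
      if (rule == 0) mo.step_bd(s); else mo.step_db(s);
      t += 1;
    }
    if (mo.m == N)
      fix_times.push_back(t);
    else if (mo.m == 0)
      loss_times.push_back(t);
    else
      ++censored;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fix_times"] = fix_times, _["loss_times"] = loss_times,
                      _["censored"] = censored);
}

// Single run with trajectory recording every `cadence` events. When
// check_interval > 0 the incremental mixed-edge count is recounted from
// scratch on that interval and any mismatch aborts (bookkeeping audit).
// [[Rcpp::export]]
List cpp_moran_single(IntegerMatrix edges, int N, double s, int rule, double cap,
                      IntegerVector init_nodes, int init_count, double cadence,
                      double check_interval) {
  Moran mo(edges, N);
  std::vector<int> init(init_nodes.begin(), init_nodes.end());
  mo.reset(mo.draw_init(init, init_count));
  std::vector<double> tv, mv, xv, sv;
  double t = 0, next_rec = 0, next_check = check_interval;
  while (true) {
    if (cadence > 0 && t >= next_rec) {
      tv.push_back(t);
      mv.push_back((double)mo.m);
      xv.push_back((double)mo.mixed);
      sv.push_back((double)mo.sdeg);
      next_rec += cadence;
    }
    if (mo.m == 0 || mo.m == N || t >= cap) break;
    if (rule == 0) mo.step_bd(s); else mo.step_db(s);
    t += 1;
    if (check_interval > 0 && t >= next_check) {
      if (mo.mixed != mo.recount_mixed())
        stop("mixed-edge bookkeeping mismatch");
      next_check += check_interval;
    }
  }
  int outcome = mo.m == N ? 1 : (mo.m == 0 ? 0 : 2);
  return List::create(_["outcome"] = outcome, _["events"] = t, _["time"] = tv,
                      _["m"] = mv, _["mixed"] = xv, _["sdeg"] = sv);
}

// Ensemble-mean trajectories of node and edge frequencies, optionally
// conditioned on fixation, plus the mixed-edge ratio p_Aa/(p_A p_a)
// aggregated by mutant count. p_Aa is the ordered-pair frequency
// mixed/(2E); together with the degree-weighted mutant frequency this is
// the convention under which p_AA = (1-p_a) - p_Aa and p_aa = p_a - p_Aa
// close exactly.
// [[Rcpp::export]]
List cpp_moran_trajectories(IntegerMatrix edges, int N, double s, int rule,
                            int nrep, double cap, double cadence,
                            bool condition_on_fixation) {
  Moran mo(edges, N);
  double twoE = 2.0 * (double)mo.E;
  std::vector<double> sum_pa, sum_pAa, sum_paw;
  std::vector<double> cnt;
  std::vector<double> ratio_sum(N + 1, 0.0), ratio_cnt(N + 1, 0.0);
  int used = 0, censored = 0;

  std::vector<double> run_pa, run_pAa, run_paw, rs(N + 1), rc(N + 1);
  for (int r = 0; r < nrep; ++r) {
    mo.reset(mo.draw_init({}, 1));
    run_pa.clear();
    run_pAa.clear();
    run_paw.clear();
    std::fill(rs.begin(), rs.end(), 0.0);
    std::fill(rc.begin(), rc.end(), 0.0);
    double t = 0, next_rec = 0;
    while (true) {
      if (t >= next_rec) {
        double pa = (double)mo.m / N;
        double pAa = (double)mo.mixed / twoE;
        run_pa.push_back(pa);
        run_pAa.push_back(pAa);
        run_paw.push_back((double)mo.sdeg / twoE);
        if (mo.m > 0 && mo.m < N) {
          rs[mo.m] += pAa / (pa * (1.0 - pa));
          rc[mo.m] += 1.0;
        }
        next_rec += cadence;
      }
      if (mo.m == 0 || mo.m == N || t >= cap) break;
      if (rule == 0) mo.step_bd(s); else mo.step_db(s);
      t += 1;
    }
    if (t >= cap && mo.m > 0 && mo.m < N) {
      ++censored;
      continue;
    }
    if (condition_on_fixation && mo.m != N) continue;
    ++used;
    if (run_pa.size() > sum_pa.size()) {
      sum_pa.resize(run_pa.size(), 0.0);
      sum_pAa.resize(run_pa.size(), 0.0);
      sum_paw.resize(run_pa.size(), 0.0);
      cnt.resize(run_pa.size(), 0.0);
    }
    for (size_t i = 0; i < run_pa.size(); ++i) {
      sum_pa[i] += run_pa[i];
      sum_pAa[i] += run_pAa[i];
      sum_paw[i] += run_paw[i];
      cnt[i] += 1.0;
    }
    for (int i = 0; i <= N; ++i) {
      ratio_sum[i] += rs[i];
      ratio_cnt[i] += rc[i];
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }

  int L = (int)sum_pa.size();
  NumericVector time(L), pa(L), pAa(L), paw(L), n(L);
  for (int i = 0; i < L; ++i) {
    time[i] = cadence * i;
    pa[i] = sum_pa[i] / cnt[i];
    pAa[i] = sum_pAa[i] / cnt[i];
    paw[i] = sum_paw[i] / cnt[i];
    n[i] = cnt[i];
  }
  NumericVector rmean(N + 1), rn(N + 1);
  for (int i = 0; i <= N; ++i) {
    rmean[i] = ratio_cnt[i] > 0 ? ratio_sum[i] / ratio_cnt[i] : NA_REAL;
    rn[i] = ratio_cnt[i];
  }
  return List::create(_["time"] = time, _["p_a"] = pa, _["p_Aa"] = pAa,
                      _["p_a_deg"] = paw, _["n"] = n, _["ratio_mean"] = rmean, _["ratio_n"] = rn,
                      _["runs_used"] = used, _["censored"] = censored);
}
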