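#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Edge endpoints arrive 0-based. An undirected edge {a,b} is keyed as
// min*n + max so membership tests are O(1).
static inline long long ekey(int a, int b, long long n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * n + hi;
}

static inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Degree-preserving double-edge swaps: (a,b),(c,d) -> (a,d),(c,b).
// Proposals creating self-loops or multi-edges are rejected and retried.
// Edges flagged frozen are never selected for swapping (they still block
// proposals that would duplicate them).
// [[Rcpp::export]]
List rewire_swaps_cpp(IntegerMatrix edges, int n_nodes, int n_swaps,
                      LogicalVector frozen, double max_prop_factor) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<long long> eset;
  eset.reserve(m * 2);
  std::vector<int> free_idx;
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0); eb[i] = edges(i, 1);
    eset.insert(ekey(ea[i], eb[i], n_nodes));
    if (!frozen[i]) free_idx.push_back(i);
  }
  int nfree = free_idx.size();
  long long done = 0, proposed = 0;
  long long max_prop = (long long)(max_prop_factor * (double)n_swaps) + 100;
  if (nfree >= 2) {
    while (done < n_swaps && proposed < max_prop) {
      ++proposed;
      int i = free_idx[runif_int(nfree)];
      int j = free_idx[runif_int(nfree)];
      if (i == j) continue;
      int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
      if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
      // propose (a,d), (c,b)
      if (a == d || c == b) continue;
      long long k1 = ekey(a, d, n_nodes), k2 = ekey(c, b, n_nodes);
      if (k1 == k2) continue;
      if (eset.count(k1) || eset.count(k2)) continue;
      eset.erase(ekey(a, b, n_nodes));
      eset.erase(ekey(c, d, n_nodes));
      eset.insert(k1); eset.insert(k2);
      ea[i] = a; eb[i] = d;
      ea[j] = c; eb[j] = b;
      ++done;
    }
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return List::create(_["edges"] = out,
                      _["n_done"] = (double)done,
                      _["n_proposed"] = (double)proposed);
}

struct Adj {
  std::vector<std::unordered_set<int> > nb;
  long long n;
  Adj(int n_nodes) : nb(n_nodes), n(n_nodes) {}
  bool has(int a, int b) const { return nb[a].count(b) > 0; }
  void add(int a, int b) { nb[a].insert(b); nb[b].insert(a); }
  void del(int a, int b) { nb[a].erase(b); nb[b].erase(a); }
  // common neighbours of a and b = triangles destroyed/created by the edge
  int cn(int a, int b) const {
    const std::unordered_set<int> &sa = nb[a].size() < nb[b].size() ? nb[a] : nb[b];
    const std::unordered_set<int> &sb = nb[a].size() < nb[b].size() ? nb[b] : nb[a];
    int c = 0;
    for (std::unordered_set<int>::const_iterator it = sa.begin(); it != sa.end(); ++it)
      if (sb.count(*it)) ++c;
    return c;
  }
};

// Simulated annealing toward a target triangle count under a fixed joint
// degree matrix. A move picks two edges, exchanges a pair of endpoints of
// equal degree (the minimal move preserving P(ki,kj)), and is accepted with
// the Metropolis probability min(exp(-dE/T), 1) where E = |T_cur - T_target|
// / T_target. Stops at energy <= tol, at max_steps, or when the windowed
// mean energy is stationary.
// [[Rcpp::export]]
List anneal_cpp(IntegerMatrix edges, int n_nodes, IntegerVector degree,
                double t_target, double t0, double cooling,
                int cooling_interval, double max_steps_d, double tol,
                int window, double stationarity_tol, int log_every,
                bool log_proposals) {
  long long max_steps = (long long)max_steps_d;
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  Adj adj(n_nodes);
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0); eb[i] = edges(i, 1);
    adj.add(ea[i], eb[i]);
  }
  // initial triangle count: sum over edges of common neighbours = 3T
  long long tri3 = 0;
  for (int i = 0; i < m; ++i) tri3 += adj.cn(ea[i], eb[i]);
  double tri = (double)(tri3 / 3);
  double energy = std::fabs(tri - t_target) / t_target;

  double temp = t0;
  long long step = 0, accepted = 0;
  std::vector<double> traj_step, traj_E;
  std::vector<double> prop_dE; std::vector<int> prop_acc;
  traj_step.push_back(0); traj_E.push_back(energy);
  double win_sum = 0, win_prev_mean = -1;
  long long win_n = 0;
  const int PROP_CAP = 200000;
  bool stationary = false;

  while (step < max_steps && energy > tol) {
    ++step;
    int i = runif_int(m), j = runif_int(m);
    bool moved = false;
    if (i != j) {
      int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
      // candidate endpoint exchanges with matching degree
      int xs[4], ys[4], nc = 0;
      if (degree[a] == degree[c] && a != c) { xs[nc] = 0; ys[nc] = 0; ++nc; }
      if (degree[a] == degree[d] && a != d) { xs[nc] = 0; ys[nc] = 1; ++nc; }
      if (degree[b] == degree[c] && b != c) { xs[nc] = 1; ys[nc] = 0; ++nc; }
      if (degree[b] == degree[d] && b != d) { xs[nc] = 1; ys[nc] = 1; ++nc; }
      if (nc > 0) {
        int pick = runif_int(nc);
        // exchange endpoint x of edge i with endpoint y of edge j
        int x = xs[pick] == 0 ? a : b;     // leaves edge i
        int xo = xs[pick] == 0 ? b : a;    // stays on edge i
        int y = ys[pick] == 0 ? c : d;     // leaves edge j
        int yo = ys[pick] == 0 ? d : c;    // stays on edge j
        // new edges: (y, xo) and (x, yo)
        bool valid = (y != xo) && (x != yo);
        // identity move: exchanging yields the same two edges back
        if (valid && y == x) valid = false;
        long long kn1 = ekey(y, xo, n_nodes), kn2 = ekey(x, yo, n_nodes);
        long long ko1 = ekey(a, b, n_nodes), ko2 = ekey(c, d, n_nodes);
        if (valid && kn1 == kn2) valid = false;
        if (valid && ((kn1 == ko1 && kn2 == ko2) || (kn1 == ko2 && kn2 == ko1)))
          valid = false;
        if (valid) {
          // multi-edge check against the graph minus the two removed edges
          bool ex1 = adj.has(y, xo) && !(kn1 == ko1 || kn1 == ko2);
          bool ex2 = adj.has(x, yo) && !(kn2 == ko1 || kn2 == ko2);
          if (!ex1 && !ex2) {
            int dtri = 0;
            dtri -= adj.cn(a, b); adj.del(a, b);
            dtri -= adj.cn(c, d); adj.del(c, d);
            dtri += adj.cn(y, xo); adj.add(y, xo);
            dtri += adj.cn(x, yo); adj.add(x, yo);
            double tri_new = tri + dtri;
            double e_new = std::fabs(tri_new - t_target) / t_target;
            double dE = e_new - energy;
            bool acc = dE <= 0 || unif_rand() < std::exp(-dE / temp);
            if (log_proposals && (long long)prop_dE.size() < PROP_CAP) {
              prop_dE.push_back(dE); prop_acc.push_back(acc ? 1 : 0);
            }
            if (acc) {
              tri = tri_new; energy = e_new; ++accepted; moved = true;
              ea[i] = y < xo ? y : xo; eb[i] = y < xo ? xo : y;
              ea[j] = x < yo ? x : yo; eb[j] = x < yo ? yo : x;
            } else {
              adj.del(x, yo); adj.del(y, xo);
              adj.add(c, d); adj.add(a, b);
            }
          }
        }
      }
    }
    (void)moved;
    if (log_every > 0 && step % log_every == 0) {
      traj_step.push_back((double)step); traj_E.push_back(energy);
    }
    if (cooling_interval > 0 && step % cooling_interval == 0) temp *= cooling;
    win_sum += energy; ++win_n;
    if (window > 0 && win_n >= window) {
      double mean_cur = win_sum / win_n;
      if (win_prev_mean >= 0 && stationarity_tol > 0) {
        double denom = win_prev_mean > 1e-12 ? win_prev_mean : 1e-12;
        if (std::fabs(mean_cur - win_prev_mean) / denom < stationarity_tol) {
          stationary = true;
          break;
        }
      }
      win_prev_mean = mean_cur;
      win_sum = 0; win_n = 0;
    }
  }
  traj_step.push_back((double)step); traj_E.push_back(energy);

  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return List::create(_["edges"] = out, _["energy"] = energy,
                      _["triangles"] = tri, _["steps"] = (double)step,
                      _["accepted"] = (double)accepted,
                      _["final_temp"] = temp,
                      _["stationary"] = stationary,
                      _["traj_step"] = traj_step, _["traj_E"] = traj_E,
                      _["prop_dE"] = prop_dE, _["prop_acc"] = prop_acc);
}
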