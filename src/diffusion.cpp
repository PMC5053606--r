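// Synchronous-epoch engine for the resource-constrained multiple-behavior
// diffusion model. Nodes are 0-based; a node's adopted behavior set is a
// bitmask over the k behaviors (k <= 25). All randomness goes through R's
// RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-12;

// lexicographic order on sorted index sets ({1,3} < {2}; {1} < {1,2}):
// a proper subset precedes its superset, otherwise the set holding the
// smallest differing index precedes.
static inline bool lex_smaller(int a, int b) {
  if (a == b) return false;
  if ((a & b) == a) return true;   // a proper subset of b
  if ((a & b) == b) return false;  // b proper subset of a
  int low = (a ^ b) & (-(a ^ b));
  return (a & low) != 0;
}

// Exhaustive knapsack over submasks of `cand`: maximize total payoff
// subject to total cost <= budget. Ties: lower total cost, then
// lexicographically smallest index set. Empty set (payoff 0) is feasible.
static int knapsack_mask(int cand, const std::vector<double>& pay,
                         const std::vector<double>& cost, double budget,
                         int k) {
  int best = 0;
  double best_pay = 0.0, best_cost = 0.0;
  if (cand == 0) return 0;
  for (int m = cand;; m = (m - 1) & cand) {
    if (m != 0) {
      double cp = 0.0, cc = 0.0;
      for (int j = 0; j < k; ++j)
        if (m & (1 << j)) { cp += pay[j]; cc += cost[j]; }
      if (cc <= budget + EPS) {
        bool take = false;
        if (cp > best_pay + EPS) take = true;
        else if (cp > best_pay - EPS) {
          if (cc < best_cost - EPS) take = true;
          else if (cc < best_cost + EPS && lex_smaller(m, best)) take = true;
        }
        if (take) { best = m; best_pay = cp; best_cost = cc; }
      }
    }
    if (m == 0) break;
  }
  return best;
}

struct Model {
  int n, k;
  std::vector<std::vector<int> > adj;
  std::vector<double> cost, util;
  double w;
  std::vector<double> mask_cost; // total cost per mask

  void init_masks() {
    mask_cost.assign(1 << k, 0.0);
    for (int m = 1; m < (1 << k); ++m)
      mask_cost[m] = mask_cost[m & (m - 1)] + cost[lowbit_index(m)];
  }
  static int lowbit_index(int m) {
    int j = 0;
    while (!(m & 1)) { m >>= 1; ++j; }
    return j;
  }
};

// social signals l_j(v) for all nodes from the previous epoch's masks
static void signals(const Model& M, const std::vector<int>& adopted,
                    std::vector<double>& l) {
  std::fill(l.begin(), l.end(), 0.0);
  for (int v = 0; v < M.n; ++v) {
    const std::vector<int>& nb = M.adj[v];
    if (nb.empty()) continue;
    double iw = 1.0 / (double)nb.size();
    for (size_t t = 0; t < nb.size(); ++t) {
      int m = adopted[nb[t]];
      for (int j = 0; j < M.k; ++j)
        if (m & (1 << j)) l[(size_t)v * M.k + j] += iw;
    }
  }
}

// One full trajectory. theta is n x k (column-major as passed from R but we
// index it flat [v + n*j]). pinned masks are forced throughout.
// init_intrinsic: epoch 0 sets every node to its utility-knapsack optimum
// (thresholds and signals bypassed) instead of installing pinned seeds.
struct RunOut {
  std::vector<int> adopted;
  int epochs;
  bool converged;
};

static RunOut run_one(const Model& M, const std::vector<double>& r,
                      const double* theta, const std::vector<int>& pinned,
                      bool sticky, bool init_intrinsic, int max_epochs) {
  int n = M.n, k = M.k;
  std::vector<int> adopted(n, 0), next(n, 0);
  std::vector<double> l((size_t)n * k, 0.0);
  std::vector<double> pay(k);

  if (init_intrinsic) {
    for (int v = 0; v < n; ++v) {
      std::vector<double> up(M.util.begin(), M.util.end());
      adopted[v] = knapsack_mask((1 << k) - 1, up, M.cost, r[v], k);
    }
  } else {
    for (int v = 0; v < n; ++v) adopted[v] = pinned[v];
  }

  int t = 0;
  bool converged = false;
  while (t < max_epochs) {
    ++t;
    signals(M, adopted, l);
    bool changed = false;
    for (int v = 0; v < n; ++v) {
      const double* lv = &l[(size_t)v * k];
      int cur = adopted[v];
      int newmask;
      if (sticky) {
        double residual = r[v] - M.mask_cost[cur];
        int cand = 0;
        for (int j = 0; j < k; ++j) {
          if (cur & (1 << j)) continue;
          if (lv[j] >= theta[v + (size_t)n * j] &&
              M.cost[j] <= residual + EPS)
            cand |= (1 << j);
        }
        for (int j = 0; j < k; ++j)
          pay[j] = M.w * M.util[j] + (1.0 - M.w) * lv[j];
        int add = knapsack_mask(cand, pay, M.cost, residual, k);
        newmask = cur | add;
      } else {
        // re-evaluation: adopted behaviors stay eligible without re-passing
        // the threshold; pinned behaviors are always retained.
        int pin = pinned[v];
        int elig = cur;
        for (int j = 0; j < k; ++j)
          if (lv[j] >= theta[v + (size_t)n * j]) elig |= (1 << j);
        elig &= ~pin;
        for (int j = 0; j < k; ++j)
          pay[j] = M.w * M.util[j] + (1.0 - M.w) * lv[j];
        double budget = r[v] - M.mask_cost[pin];
        int add = knapsack_mask(elig, pay, M.cost, budget, k);
        newmask = pin | add;
      }
      next[v] = newmask;
      if (newmask != cur) changed = true;
    }
    std::swap(adopted, next);
    if (!changed) { converged = true; break; }
  }

  RunOut out;
  out.adopted = adopted;
  out.epochs = t;
  out.converged = converged;
  return out;
}

static Model build_model(const List& adj, const NumericVector& cost,
                         const NumericVector& util, double w) {
  Model M;
  M.n = adj.size();
  M.k = cost.size();
  if (M.k > 25) stop("at most 25 behaviors are supported");
  M.adj.resize(M.n);
  for (int v = 0; v < M.n; ++v) {
    IntegerVector nb = adj[v];
    M.adj[v].assign(nb.begin(), nb.end());
  }
  M.cost.assign(cost.begin(), cost.end());
  M.util.assign(util.begin(), util.end());
  M.w = w;
  M.init_masks();
  return M;
}

// [[Rcpp::export(name = ".cpp_run_diffusion")]]
List cpp_run_diffusion(List adj, NumericVector r, NumericMatrix theta,
                       IntegerVector pinned, NumericVector cost,
                       NumericVector util, double w, bool sticky,
                       bool init_intrinsic, int max_epochs) {
  Model M = build_model(adj, cost, util, w);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> pin(pinned.begin(), pinned.end());
  RunOut out = run_one(M, rv, theta.begin(), pin, sticky, init_intrinsic,
                       max_epochs);
  NumericVector s(M.n);
  int participation = 0, adoption = 0;
  for (int v = 0; v < M.n; ++v) {
    s[v] = M.mask_cost[out.adopted[v]];
    if (out.adopted[v]) ++participation;
    for (int j = 0; j < M.k; ++j)
      if (out.adopted[v] & (1 << j)) ++adoption;
  }
  return List::create(_["adopted"] = wrap(out.adopted), _["s"] = s,
                      _["epochs"] = out.epochs,
                      _["converged"] = out.converged,
                      _["participation"] = participation,
                      _["adoption"] = adoption);
}

// Monte-Carlo metrics over `runs` threshold resamples (theta ~ U(0,1)
// i.i.d., drawn from R's RNG). Returns runs x 4:
// participation, adoption, utilization, converged.
// [[Rcpp::export(name = ".cpp_mc_metrics")]]
NumericMatrix cpp_mc_metrics(List adj, NumericVector r, IntegerVector pinned,
                             NumericVector cost, NumericVector util,
                             double w, bool sticky, bool init_intrinsic,
                             int max_epochs, int runs) {
  Model M = build_model(adj, cost, util, w);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> pin(pinned.begin(), pinned.end());
  int n = M.n, k = M.k;
  double total_r = 0.0;
  for (int v = 0; v < n; ++v) total_r += rv[v];
  std::vector<double> theta((size_t)n * k);
  NumericMatrix out(runs, 4);
  for (int it = 0; it < runs; ++it) {
    for (int j = 0; j < k; ++j)
      for (int v = 0; v < n; ++v) theta[v + (size_t)n * j] = unif_rand();
    RunOut res = run_one(M, rv, &theta[0], pin, sticky, init_intrinsic,
                         max_epochs);
    int participation = 0, adoption = 0;
    double spent = 0.0;
    for (int v = 0; v < n; ++v) {
      int m = res.adopted[v];
      if (m) ++participation;
      spent += M.mask_cost[m];
      for (int j = 0; j < k; ++j)
        if (m & (1 << j)) ++adoption;
    }
    out(it, 0) = participation;
    out(it, 1) = adoption;
    out(it, 2) = total_r > 0 ? spent / total_r : NA_REAL;
    out(it, 3) = res.converged ? 1.0 : 0.0;
  }
  return out;
}

// Per-node activation counts over `runs` threshold resamples (sticky or
// re-evaluation); used for distributional comparisons with the live-edge
// process.
// [[Rcpp::export(name = ".cpp_mc_activation")]]
IntegerVector cpp_mc_activation(List adj, NumericVector r,
                                IntegerVector pinned, NumericVector cost,
                                NumericVector util, double w, bool sticky,
                                int max_epochs, int runs) {
  Model M = build_model(adj, cost, util, w);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> pin(pinned.begin(), pinned.end());
  int n = M.n, k = M.k;
  std::vector<double> theta((size_t)n * k);
  IntegerVector counts(n);
  for (int it = 0; it < runs; ++it) {
    for (int j = 0; j < k; ++j)
      for (int v = 0; v < n; ++v) theta[v + (size_t)n * j] = unif_rand();
    RunOut res = run_one(M, rv, &theta[0], pin, sticky, false, max_epochs);
    for (int v = 0; v < n; ++v)
      if (res.adopted[v]) ++counts[v];
  }
  return counts;
}
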