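#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Backward coalescent conditioned on a recorded forward demography.
//
// The forward run gives per-generation deme sizes N[tau, cell]
// (tau = 0..t_exp, row-major from R as a matrix) and emigrant counts
// E[tau, cell, k] sent from `cell` to its k-th cardinal neighbour during the
// step tau -> tau + 1. Backward in time, lineages co-located in a deme at
// generation tau coalesce with probability 1/N (implemented by uniform
// parent assignment, so every pair collides with probability 1/N), then
// trace their deme of origin: the probability that a lineage now in deme j
// immigrated from neighbour i during the step is E[tau-1, i -> j] / N[tau, j].
//
// At tau = 0 surviving lineages drop into one of two panmictic ancestral
// pools (assignment per cell precomputed in R by nearest origin) with
// continuous-time pairwise coalescence at rate 1/size until t_div, when the
// pools merge into a single ancestor of summed size.

// [[Rcpp::export(name = ".spatial_coal_cpp")]]
List spatial_coal_cpp(NumericMatrix N, NumericVector E, IntegerMatrix nb,
                      IntegerVector leaf_cell, IntegerVector pool_of_cell,
                      double anc_north, double anc_south,
                      int t_exp, int t_div) {
  const int n = leaf_cell.size();
  const int ncell = N.ncol();
  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector time(n_nodes);
  IntegerVector node_deme(n_nodes, -1);
  int next_node = n;
  int n_clip = 0;

  std::vector<int> act(n);      // active node ids
  std::vector<int> deme(n);     // current cell of each active lineage
  for (int i = 0; i < n; ++i) {
    act[i] = i;
    deme[i] = leaf_cell[i];
    time[i] = 0.0;
    node_deme[i] = leaf_cell[i];
  }
  int k = n;

  auto Eval = [&](int tau, int cell, int dir) {
    return E[tau + (int64_t)t_exp * (cell + (int64_t)ncell * dir)];
  };

  // ---- spatial phase: generations t_exp down to 1 ----
  for (int g = t_exp; g >= 1 && k > 1; --g) {
    // coalescence at generation g: uniform parent assignment within demes
    std::unordered_map<int, std::vector<int>> by_deme;
    for (int i = 0; i < k; ++i) by_deme[deme[i]].push_back(i);
    std::vector<int> removed;
    for (auto &kv : by_deme) {
      std::vector<int> &idx = kv.second;
      if ((int)idx.size() < 2) continue;
      double Nd = N(g, kv.first);
      if (Nd < 1.0) Nd = 1.0;
      long Ni = (long)std::ceil(Nd);
      std::unordered_map<long, int> parent_slot;  // parent id -> lineage idx
      double sub = 0.0;                            // tie-break offset within the generation
      for (int ii : idx) {
        long p = (long)std::floor(R::runif(0.0, (double)Ni));
        if (p >= Ni) p = Ni - 1;
        auto it = parent_slot.find(p);
        if (it == parent_slot.end()) {
          parent_slot[p] = ii;
        } else {
          int jj = it->second;
          int node = next_node++;
          sub += 1.0 / (idx.size() + 1.0);
          // backward time inside (t_exp - g + 0.5, t_exp - g + 1): strictly
          // after the previous generation's events, strictly before the
          // next, with within-generation ties broken by `sub`
          time[node] = (double)(t_exp - g) + 0.5 + sub * 0.5;
          node_deme[node] = kv.first;
          parent[act[ii]] = node;
          parent[act[jj]] = node;
          act[jj] = node;          // merged lineage keeps slot jj
          parent_slot[p] = jj;
          removed.push_back(ii);
        }
      }
    }
    if (!removed.empty()) {
      std::sort(removed.begin(), removed.end(), std::greater<int>());
      for (int ii : removed) {
        act.erase(act.begin() + ii);
        deme.erase(deme.begin() + ii);
      }
      k = (int)act.size();
    }
    if (k <= 1) break;
    // backward migration into generation g - 1
    int tau = g - 1;
    for (int i = 0; i < k; ++i) {
      int j = deme[i];
      double Nj = N(g, j);
      if (Nj < 1.0) Nj = 1.0;
      double p[4], tot = 0.0;
      int src[4];
      for (int d = 0; d < 4; ++d) {
        p[d] = 0.0;
        src[d] = nb(j, d);
        if (src[d] >= 0) {
          // immigrants from src arrived via src's opposite direction slot
          double ein = Eval(tau, src[d], (d + 2) % 4);
          p[d] = ein / Nj;
          tot += p[d];
        }
      }
      if (tot > 1.0) {  // can occur in deterministic mode with extreme growth
        for (int d = 0; d < 4; ++d) p[d] /= tot;
        tot = 1.0;
        ++n_clip;
      }
      double u = R::runif(0.0, 1.0);
      double acc = 0.0;
      for (int d = 0; d < 4; ++d) {
        acc += p[d];
        if (u < acc) { deme[i] = src[d]; break; }
      }
      // else: lineage stays in j
    }
  }

  // ---- ancestral pools: continuous time from t_exp backwards ----
  if (k > 1) {
    std::vector<int> pool(k);
    for (int i = 0; i < k; ++i) pool[i] = pool_of_cell[deme[i]];
    double t = (double)t_exp;
    bool merged = false;
    while (k > 1) {
      int kn = 0, ks = 0;
      for (int i = 0; i < k; ++i) (pool[i] == 0 ? kn : ks)++;
      double rn, rs;
      if (!merged) {
        rn = kn * (kn - 1) / 2.0 / anc_north;
        rs = ks * (ks - 1) / 2.0 / anc_south;
      } else {
        rn = k * (k - 1) / 2.0 / (anc_north + anc_south);
        rs = 0.0;
      }
      double rate = rn + rs;
      double dt = (rate > 0) ? R::rexp(1.0 / rate) : R_PosInf;
      if (!merged && t + dt >= (double)t_div) {
        t = (double)t_div;
        merged = true;
        for (int i = 0; i < k; ++i) pool[i] = 0;
        continue;
      }
      if (!R_FINITE(dt)) stop("ancestral coalescent stalled");
      t += dt;
      int target_pool = (!merged && R::runif(0.0, rate) >= rn) ? 1 : 0;
      std::vector<int> idx;
      for (int i = 0; i < k; ++i) if (merged || pool[i] == target_pool) idx.push_back(i);
      int a = (int)std::floor(R::runif(0.0, (double)idx.size()));
      int b = (int)std::floor(R::runif(0.0, (double)idx.size() - 1));
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      int node = next_node++;
      time[node] = t;
      node_deme[node] = -1 - pool[ia];
      parent[act[ia]] = node;
      parent[act[ib]] = node;
      act[ia] = node;
      int drop = ib;
      act.erase(act.begin() + drop);
      deme.erase(deme.begin() + drop);
      pool.erase(pool.begin() + drop);
      k = (int)act.size();
    }
  }

  return List::create(_["parent"] = parent, _["time"] = time,
                      _["deme"] = node_deme, _["n_clipped"] = n_clip);
}
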