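#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Continuous-time structured coalescent over piecewise-constant epochs.
//
// Demography is a list of epochs with start times (generations before
// present), per-deme haploid sizes and a backward migration-rate matrix
// (per lineage per generation). Epoch boundaries may carry "join" moves
// (all lineages of deme `from` relocate to deme `to`), which is how
// divergence events are expressed backward in time.
//
// Per sequence a genealogy is simulated and infinite-sites mutations are
// dropped on each branch (Poisson with mean branch_length * theta, theta =
// mu_per_bp * seq_length); every mutation increments the unfolded joint SFS
// cell given by the branch's descendant counts in the two sampled groups.

struct Lineage {
  int deme;
  int d1, d2;     // descendant sample counts in group 1 / group 2
  double birth;   // time the lineage (node) was created
};

// When `expected` is true, each branch contributes its expected mutation
// mass (length * theta) instead of a Poisson draw — a Rao-Blackwellized
// estimate of the expected SFS with much lower variance per genealogy.
// [[Rcpp::export(name = ".coal_sfs_cpp")]]
NumericMatrix coal_sfs_cpp(IntegerVector leaf_deme, IntegerVector leaf_group,
                           NumericVector epoch_start, NumericMatrix sizes,
                           NumericVector mig, IntegerMatrix joins,
                           int n_seq, double theta, bool expected = false) {
  const int n = leaf_deme.size();
  const int n_epoch = epoch_start.size();
  const int D = sizes.ncol();
  int n1 = 0, n2 = 0;
  for (int i = 0; i < n; ++i) (leaf_group[i] == 1 ? n1 : n2)++;
  NumericMatrix sfs(n1 + 1, n2 + 1);

  // mig is flattened [epoch, from, to]
  auto mrate = [&](int e, int from, int to) {
    return mig[e + n_epoch * (from + D * to)];
  };

  std::vector<Lineage> lin;
  lin.reserve(2 * n);
  std::vector<int> kd(D);

  for (int s = 0; s < n_seq; ++s) {
    lin.clear();
    for (int i = 0; i < n; ++i) {
      Lineage L;
      L.deme = leaf_deme[i];
      L.d1 = leaf_group[i] == 1 ? 1 : 0;
      L.d2 = leaf_group[i] == 2 ? 1 : 0;
      L.birth = 0.0;
      lin.push_back(L);
    }
    double t = 0.0;
    int epoch = 0;

    auto apply_joins = [&](int e) {
      for (int j = 0; j < joins.nrow(); ++j) {
        if (joins(j, 0) == e) {
          for (size_t i = 0; i < lin.size(); ++i)
            if (lin[i].deme == joins(j, 1)) lin[i].deme = joins(j, 2);
        }
      }
    };

    while (lin.size() > 1) {
      // advance epoch pointer, applying boundary joins
      while (epoch + 1 < n_epoch && t >= epoch_start[epoch + 1] - 1e-12) {
        ++epoch;
        apply_joins(epoch);
      }
      std::fill(kd.begin(), kd.end(), 0);
      for (size_t i = 0; i < lin.size(); ++i) kd[lin[i].deme]++;

      double coal_tot = 0.0, mig_tot = 0.0;
      for (int d = 0; d < D; ++d) {
        if (kd[d] >= 2) coal_tot += kd[d] * (kd[d] - 1) / 2.0 / sizes(epoch, d);
        if (kd[d] >= 1) {
          double out = 0.0;
          for (int d2 = 0; d2 < D; ++d2) if (d2 != d) out += mrate(epoch, d, d2);
          mig_tot += kd[d] * out;
        }
      }
      double rate = coal_tot + mig_tot;
      double dt = (rate > 0) ? R::rexp(1.0 / rate) : R_PosInf;
      double t_next = (epoch + 1 < n_epoch) ? epoch_start[epoch + 1] : R_PosInf;
      if (t + dt >= t_next) {
        if (!R_FINITE(t_next)) stop("structured coalescent stalled: zero total rate in final epoch");
        t = t_next;
        continue;
      }
      t += dt;
      double u = R::runif(0.0, rate);
      if (u < coal_tot) {
        // pick deme, then a uniform pair within it
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < D; ++dd) {
          if (kd[dd] >= 2) {
            acc += kd[dd] * (kd[dd] - 1) / 2.0 / sizes(epoch, dd);
            if (u < acc) { d = dd; break; }
          }
        }
        if (d < 0) d = D - 1;
        int a = (int)std::floor(R::runif(0.0, kd[d]));
        int b = (int)std::floor(R::runif(0.0, kd[d] - 1));
        if (b >= a) ++b;
        int ia = -1, ib = -1, cnt = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          if (lin[i].deme == d) {
            if (cnt == a) ia = (int)i;
            if (cnt == b) ib = (int)i;
            ++cnt;
          }
        }
        // drop mutations on both child branches
        for (int ch : {ia, ib}) {
          double len = t - lin[ch].birth;
          if (expected) {
            sfs(lin[ch].d1, lin[ch].d2) += len * theta;
          } else {
            int nm = (int)R::rpois(len * theta);
            if (nm > 0) sfs(lin[ch].d1, lin[ch].d2) += nm;
          }
        }
        Lineage P;
        P.deme = d;
        P.d1 = lin[ia].d1 + lin[ib].d1;
        P.d2 = lin[ia].d2 + lin[ib].d2;
        P.birth = t;
        if (ia < ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ia);
        lin.erase(lin.begin() + ib);
        lin.push_back(P);
      } else {
        // migration event
        u -= coal_tot;
        double acc = 0.0;
        int from = -1, to = -1;
        for (int d = 0; d < D && from < 0; ++d) {
          if (kd[d] < 1) continue;
          for (int d2 = 0; d2 < D; ++d2) {
            if (d2 == d) continue;
            acc += kd[d] * mrate(epoch, d, d2);
            if (u < acc) { from = d; to = d2; break; }
          }
        }
        if (from < 0) { from = 0; to = 1; }
        int pick = (int)std::floor(R::runif(0.0, kd[from]));
        int cnt = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          if (lin[i].deme == from) {
            if (cnt == pick) { lin[i].deme = to; break; }
            ++cnt;
          }
        }
      }
    }
  }
  return sfs;
}
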