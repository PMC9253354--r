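#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact continuous-time simulation of the multi-stage process with
// generations.  Compartments are (generation g, stage j); a compartment
// holding n cells contributes hazard n*lambda_g for stage advance (or
// division from the last stage, sending two daughters to stage 1 of
// generation g+1) and n*mu_g for death.  Hazards are aggregated per
// compartment -- cells within a compartment are exchangeable, so this is
// distribution-identical to tracking individual cells.  Both division and
// death act on a uniformly chosen cell of the selected generation because
// per-cell rates do not depend on the stage within a generation.
//
// Generations are extended on demand; rates for generations beyond the
// supplied vectors follow the supplied extension rule (stage count ext_N,
// birth rate ext_lambda, death rate ext_alpha * g, or ext_mu_const when
// ext_alpha < 0).
//
// Uses R's RNG (seed with set.seed() before calling).

struct MsgSim {
  std::vector<int> Ng;
  std::vector<double> lam, mu;
  std::vector<std::vector<double>> cnt; // cell counts per (g, j)
  std::vector<double> ntot;             // cells per generation
  int ext_N;
  double ext_lambda, ext_alpha, ext_mu_const;
  double H = 0.0, total = 0.0;

  void ensure_gen(size_t g) {
    while (cnt.size() <= g) {
      size_t gnew = cnt.size();
      if (gnew >= Ng.size()) {
        Ng.push_back(ext_N);
        lam.push_back(ext_lambda);
        mu.push_back(ext_alpha >= 0 ? ext_alpha * (double)gnew : ext_mu_const);
      }
      cnt.push_back(std::vector<double>(Ng[gnew], 0.0));
      ntot.push_back(0.0);
    }
  }
};

// [[Rcpp::export]]
List cpp_msg_gillespie(IntegerVector Ng, NumericVector lambda, NumericVector mu,
                       int ext_N, double ext_lambda, double ext_alpha,
                       double ext_mu_const, double C0,
                       NumericVector sample_times, double cell_cap,
                       double escape_threshold) {
  MsgSim S;
  S.Ng.assign(Ng.begin(), Ng.end());
  S.lam.assign(lambda.begin(), lambda.end());
  S.mu.assign(mu.begin(), mu.end());
  S.ext_N = ext_N;
  S.ext_lambda = ext_lambda;
  S.ext_alpha = ext_alpha;
  S.ext_mu_const = ext_mu_const;
  S.ensure_gen(0);
  S.cnt[0][0] = C0;
  S.ntot[0] = C0;
  S.total = C0;
  S.H = C0 * (S.lam[0] + S.mu[0]);

  const int nt = sample_times.size();
  std::vector<std::vector<std::vector<double>>> snaps;
  snaps.reserve(nt);
  int si = 0;
  double t = 0.0;
  bool capped = false, escaped = false;
  // record any sampling time at or before t = 0
  while (si < nt && sample_times[si] <= 0.0) { snaps.push_back(S.cnt); ++si; }

  while (si < nt) {
    if (S.H <= 0.0 || S.total <= 0.0) { // extinct: state frozen
      while (si < nt) { snaps.push_back(S.cnt); ++si; }
      break;
    }
    if (escape_threshold > 0 && S.total >= escape_threshold) {
      escaped = true;
      break;
    }
    double t_next = t + R::exp_rand() / S.H;
    while (si < nt && sample_times[si] <= t_next) {
      snaps.push_back(S.cnt);
      ++si;
    }
    if (si >= nt && escape_threshold <= 0) { t = t_next; break; }
    t = t_next;

    // pick generation proportional to ntot[g] * (lambda_g + mu_g)
    double u = unif_rand() * S.H, accg = 0.0;
    size_t g = 0;
    for (; g < S.cnt.size(); ++g) {
      accg += S.ntot[g] * (S.lam[g] + S.mu[g]);
      if (u <= accg) break;
    }
    if (g >= S.cnt.size()) g = S.cnt.size() - 1; // float-slop guard
    while (S.ntot[g] <= 0) --g;

    // uniformly chosen cell within the generation
    double uc = unif_rand() * S.ntot[g], accj = 0.0;
    int j = 0, ng = S.Ng[g];
    for (; j < ng; ++j) {
      accj += S.cnt[g][j];
      if (uc <= accj) break;
    }
    if (j >= ng) j = ng - 1;
    while (S.cnt[g][j] <= 0) --j;

    double lg = S.lam[g], mg = S.mu[g];
    bool death = (unif_rand() * (lg + mg) < mg);
    if (death) {
      S.cnt[g][j] -= 1;
      S.ntot[g] -= 1;
      S.total -= 1;
      S.H -= (lg + mg);
    } else if (j + 1 < ng) {
      S.cnt[g][j] -= 1;
      S.cnt[g][j + 1] += 1;
    } else { // division into generation g + 1
      S.cnt[g][j] -= 1;
      S.ntot[g] -= 1;
      S.ensure_gen(g + 1);
      S.cnt[g + 1][0] += 2;
      S.ntot[g + 1] += 2;
      S.total += 1;
      S.H += 2.0 * (S.lam[g + 1] + S.mu[g + 1]) - (lg + mg);
      if (S.total > cell_cap) { capped = true; break; }
    }
  }

  // assemble snapshots (earlier snapshots may span fewer generations)
  size_t Gmax = S.cnt.size();
  int dim = 0;
  std::vector<int> off(Gmax);
  for (size_t g = 0; g < Gmax; ++g) { off[g] = dim; dim += S.Ng[g]; }
  NumericMatrix counts(dim, nt);
  IntegerVector gen(dim), stage(dim);
  for (size_t g = 0; g < Gmax; ++g)
    for (int j = 0; j < S.Ng[g]; ++j) {
      gen[off[g] + j] = (int)g;
      stage[off[g] + j] = j + 1;
    }
  for (int k = 0; k < (int)snaps.size(); ++k)
    for (size_t g = 0; g < snaps[k].size(); ++g)
      for (int j = 0; j < (int)snaps[k][g].size(); ++j)
        counts(off[g] + j, k) = snaps[k][g][j];

  return List::create(_["generation"] = gen, _["stage"] = stage,
                      _["counts"] = counts, _["capped"] = capped,
                      _["escaped"] = escaped, _["extinct"] = (S.total <= 0.0),
                      _["final_total"] = S.total, _["final_time"] = t,
                      _["n_recorded"] = (int)snaps.size());
}
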