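#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1D lattice loop-extrusion Monte Carlo. Extruders are (left, right) leg
// pairs on [0, n_monomers); legs perform +-1 random-walk proposals accepted
// by Metropolis under E = -c_fold * sum ln(span) + c_cross * #crossings.
// CTCF barriers act kinetically: a leg occupying a barrier monomer is
// vetoed, with probability equal to the barrier strength for its direction
// of motion, when it tries to leave that monomer. Fast-class extruders make
// fast_multiplier proposals per sweep. Temperature anneals linearly.
// Randomness comes from R's RNG so set.seed() makes runs bit-identical.

static inline bool crossing(int l1, int r1, int l2, int r2) {
  return (l1 < l2 && l2 < r1 && r1 < r2) || (l2 < l1 && l1 < r2 && r2 < r1);
}

static int crossings_with_others(const std::vector<int>& L,
                                 const std::vector<int>& R,
                                 int i, int li, int ri) {
  int c = 0;
  for (size_t j = 0; j < L.size(); ++j) {
    if ((int)j == i) continue;
    if (crossing(li, ri, L[j], R[j])) ++c;
  }
  return c;
}

// [[Rcpp::export]]
List cpp_run_extrusion(int n_monomers, int n_steps, int sample_every,
                       int burn_in, double t_init, double t_final,
                       int n_slow, int n_fast, int fast_multiplier,
                       double c_fold, double c_cross, double unbind_prob,
                       NumericVector left_block, NumericVector right_block) {
  const int N = n_slow + n_fast;
  std::vector<int> L(N), R(N);
  for (int i = 0; i < N; ++i) {
    int x = (int)std::floor(unif_rand() * (n_monomers - 1));
    if (x > n_monomers - 2) x = n_monomers - 2;
    L[i] = x; R[i] = x + 1;
  }

  int expected = 0;
  for (int s = burn_in + 1; s <= n_steps; ++s)
    if ((s - burn_in) % sample_every == 0) ++expected;
  IntegerMatrix samples(expected * N, 5);  // sample, step, extruder, left, right
  int row = 0, sample_idx = 0;

  for (int step = 1; step <= n_steps; ++step) {
    const double T = t_init + (t_final - t_init) * ((double)step / n_steps);
    for (int i = 0; i < N; ++i) {
      const bool fast = i >= n_slow;
      // Unbind/rebind: teleport to a random loading site, Metropolis on dE.
      if (unbind_prob > 0 && unif_rand() < unbind_prob) {
        int x = (int)std::floor(unif_rand() * (n_monomers - 1));
        if (x > n_monomers - 2) x = n_monomers - 2;
        double dE = c_fold * std::log((double)(R[i] - L[i]))
          - c_cross * crossings_with_others(L, R, i, L[i], R[i])
          + c_cross * crossings_with_others(L, R, i, x, x + 1);
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          L[i] = x; R[i] = x + 1;
        }
      }
      const int reps = fast ? fast_multiplier : 1;
      for (int rep = 0; rep < reps; ++rep) {
        const bool move_left_leg = unif_rand() < 0.5;
        const int dir = (unif_rand() < 0.5) ? -1 : 1;
        const int p = move_left_leg ? L[i] : R[i];
        const int pn = p + dir;
        if (move_left_leg) {
          if (pn < 0 || pn >= R[i]) continue;
        } else {
          if (pn > n_monomers - 1 || pn <= L[i]) continue;
        }
        const double block = (dir < 0) ? left_block[p] : right_block[p];
        if (block > 0 && unif_rand() < block) continue;
        const int nl = move_left_leg ? pn : L[i];
        const int nr = move_left_leg ? R[i] : pn;
        double dE = -c_fold * (std::log((double)(nr - nl)) -
                               std::log((double)(R[i] - L[i])));
        if (c_cross != 0)
          dE += c_cross * (crossings_with_others(L, R, i, nl, nr) -
                           crossings_with_others(L, R, i, L[i], R[i]));
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          L[i] = nl; R[i] = nr;
        }
      }
    }
    if (step > burn_in && (step - burn_in) % sample_every == 0) {
      ++sample_idx;
      for (int i = 0; i < N; ++i) {
        samples(row, 0) = sample_idx;
        samples(row, 1) = step;
        samples(row, 2) = i + 1;
        samples(row, 3) = L[i];
        samples(row, 4) = R[i];
        ++row;
      }
    }
  }

  // Exact final energy, recomputed from scratch as a bookkeeping check.
  double E = 0;
  for (int i = 0; i < N; ++i) E -= c_fold * std::log((double)(R[i] - L[i]));
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (crossing(L[i], R[i], L[j], R[j])) E += c_cross;

  IntegerVector fl(N), fr(N);
  for (int i = 0; i < N; ++i) { fl[i] = L[i]; fr[i] = R[i]; }
  return List::create(_["samples"] = samples, _["final_left"] = fl,
                      _["final_right"] = fr, _["final_energy"] = E,
                      _["n_samples"] = sample_idx);
}
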