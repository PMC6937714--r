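#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Markov-chain exact test of Hardy-Weinberg equilibrium, conditional on
// allele counts. State = arrangement of the 2n gene copies into n diploid
// individuals; a proposal swaps one random allele slot between two random
// individuals. The uniform distribution over arrangements (= the exact
// conditional null, by exchangeability of gametes) is invariant under these
// symmetric transpositions, so every proposal is accepted and the chain is
// a random-transposition walk.
//
// Statistic per state:
//   alt 1 (two-sided): conditional table probability pi ~ 2^h / prod n_ab!
//     (states with pi <= pi_obs count toward p)
//   alt 2 (heterozygote excess):    h >= h_obs
//   alt 3 (heterozygote deficiency): h <= h_obs
//
// p is the mean of batch means; the Monte Carlo SE is their sd/sqrt(B).
//
// [[Rcpp::export]]
NumericVector hwe_mc_chain(IntegerVector a, IntegerVector b, int k,
                           int dememorization, int batches, int iterations,
                           int alt) {
  const int n = a.size();
  std::vector<int> A(n), B(n);
  std::vector<double> lfac(2 * n + 2);
  lfac[0] = 0.0;
  for (int i = 1; i < (int)lfac.size(); ++i)
    lfac[i] = lfac[i - 1] + std::log((double)i);

  // genotype counts, upper-triangular storage idx = i*k + j with i<=j
  std::vector<int> cnt(k * k, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    A[i] = a[i] - 1; B[i] = b[i] - 1;
    int x = A[i] < B[i] ? A[i] : B[i];
    int y = A[i] < B[i] ? B[i] : A[i];
    cnt[x * k + y]++;
    if (x != y) ++h;
  }
  double slf = 0.0;  // sum over cells of log(n_ab!)
  for (int c = 0; c < k * k; ++c) slf += lfac[cnt[c]];
  const double log2 = std::log(2.0);
  double logpi = h * log2 - slf;
  const double logpi_obs = logpi + 1e-9;
  const int h_obs = h;

  long total_steps = (long)dememorization +
                     (long)batches * (long)iterations;
  int bdone = 0;
  long in_batch = 0;
  double bsum = 0.0, msum = 0.0, m2sum = 0.0;

  for (long step = 0; step < total_steps; ++step) {
    // choose two distinct individuals and one slot of each
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    int j = (int)(unif_rand() * (n - 1)); if (j == n - 1) j = n - 2;
    if (j >= i) ++j;
    bool si = unif_rand() < 0.5, sj = unif_rand() < 0.5;
    int &ai = si ? A[i] : B[i];
    int &aj = sj ? A[j] : B[j];
    if (ai != aj) {
      // remove old genotypes of i and j from the table
      int xi = A[i] < B[i] ? A[i] : B[i], yi = A[i] < B[i] ? B[i] : A[i];
      int xj = A[j] < B[j] ? A[j] : B[j], yj = A[j] < B[j] ? B[j] : A[j];
      slf -= lfac[cnt[xi * k + yi]]; cnt[xi * k + yi]--;
      slf += lfac[cnt[xi * k + yi]];
      slf -= lfac[cnt[xj * k + yj]]; cnt[xj * k + yj]--;
      slf += lfac[cnt[xj * k + yj]];
      if (xi != yi) --h;
      if (xj != yj) --h;
      int t = ai; ai = aj; aj = t;
      xi = A[i] < B[i] ? A[i] : B[i]; yi = A[i] < B[i] ? B[i] : A[i];
      xj = A[j] < B[j] ? A[j] : B[j]; yj = A[j] < B[j] ? B[j] : A[j];
      slf -= lfac[cnt[xi * k + yi]]; cnt[xi * k + yi]++;
      slf += lfac[cnt[xi * k + yi]];
      slf -= lfac[cnt[xj * k + yj]]; cnt[xj * k + yj]++;
      slf += lfac[cnt[xj * k + yj]];
      if (xi != yi) ++h;
      if (xj != yj) ++h;
      logpi = h * log2 - slf;
    }
    if (step < dememorization) continue;
    bool hit;
    if (alt == 1)      hit = logpi <= logpi_obs;
    else if (alt == 2) hit = h >= h_obs;
    else               hit = h <= h_obs;
    bsum += hit ? 1.0 : 0.0;
    if (++in_batch == iterations) {
      double bm = bsum / iterations;
      msum += bm; m2sum += bm * bm;
      bsum = 0.0; in_batch = 0; ++bdone;
    }
  }
  double p = msum / bdone;
  double var = (m2sum - msum * msum / bdone) / (bdone - 1);
  double se = std::sqrt(var > 0 ? var / bdone : 0.0);
  return NumericVector::create(p, se);
}
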