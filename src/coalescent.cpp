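// Batch coalescent engine: exponential-growth genealogies with
// infinite-sites mutation, returning per-replicate summaries only.
// Time in 4N0 units; k-lineage coalescence rate k(k-1) e^{alpha t}.
// Uses R's RNG so results are governed by set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
DataFrame coal_batch_cpp(int n, NumericVector theta, NumericVector alpha) {
  const int reps = theta.size();
  IntegerVector S(reps);
  NumericVector pi(reps), tmrca(reps), ttot(reps);
  std::vector<int> lv(n);
  std::vector<double> bt(n);
  std::vector<double> blen;
  std::vector<int> bcnt;
  const double pair_denom = (double)n * (n - 1) / 2.0;

  for (int r = 0; r < reps; ++r) {
    const double a = alpha[r];
    int k = n;
    std::fill(lv.begin(), lv.end(), 1);
    std::fill(bt.begin(), bt.end(), 0.0);
    blen.clear();
    bcnt.clear();
    double t = 0.0;
    while (k > 1) {
      const double e = R::exp_rand();
      const double rate = (double)k * (k - 1);
      double dt;
      if (a == 0.0) {
        dt = e / rate;
      } else {
        // hazard inversion in log space: stable for large alpha*t
        dt = std::log1p(a * e * std::exp(-a * t) / rate) / a;
      }
      t += dt;
      int i = (int)(unif_rand() * k);
      if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1));
      if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      blen.push_back(t - bt[i]);
      bcnt.push_back(lv[i]);
      blen.push_back(t - bt[j]);
      bcnt.push_back(lv[j]);
      lv[i] += lv[j];
      bt[i] = t;
      lv[j] = lv[k - 1];
      bt[j] = bt[k - 1];
      --k;
    }
    double total = 0.0;
    for (double b : blen) total += b;
    tmrca[r] = t;
    ttot[r] = total;
    // Poisson thinning: per-branch mutation counts are independent
    // Poisson(theta * length), equivalent to placing Poisson(theta * total)
    // mutations proportionally to branch length, at O(n) per replicate
    int m = 0;
    double pr = 0.0;
    for (size_t b = 0; b < blen.size(); ++b) {
      const int mb = (int)R::rpois(theta[r] * blen[b]);
      if (mb > 0) {
        m += mb;
        const int carriers = bcnt[b];
        pr += (double)mb * carriers * (n - carriers) / pair_denom;
      }
    }
    S[r] = m;
    pi[r] = pr;
  }
  return DataFrame::create(_["S"] = S, _["pi_region"] = pi,
                           _["t_mrca"] = tmrca, _["t_total"] = ttot);
}
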