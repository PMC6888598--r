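#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// One-sided Fisher p for the 2x2 table with x1 successes of n1 trials in
// group 1 and x2 of n2 in group 2, alternative p1 > p2: conditional on the
// success margin k = x1 + x2, P(X1 >= x1) under the hypergeometric law.
static double fisher_one_sided(int x1, int n1, int x2, int n2) {
  int k = x1 + x2;
  if (k == 0) return 1.0;
  // lower_tail = FALSE, log_p = FALSE
  return R::phyper((double)(x1 - 1), (double)k, (double)(n1 + n2 - k),
                   (double)n1, 0, 0);
}

// [[Rcpp::export(name = ".fisher_one_sided_cpp")]]
double fisher_one_sided_cpp(int x1, int n1, int x2, int n2) {
  return fisher_one_sided(x1, n1, x2, n2);
}

// Boschloo's one-sided unconditional exact p-value.
//
// Ordering statistic is the one-sided Fisher p; the rejection region for the
// observed table is every table (i, j) with Fisher p <= the observed one
// (with a small tie tolerance).  The p-value is the supremum over the
// nuisance common success probability pi of the binomial probability of that
// region; the supremum is taken over the supplied grid of pi values.
//
// Because the one-sided Fisher p is non-decreasing in j for fixed i
// (hypergeometric tail stochastically increasing in the success margin),
// the region is {(i, j) : j <= J[i]}, so each grid point costs O(n1 + n2).
// [[Rcpp::export(name = ".boschloo_p_cpp")]]
double boschloo_p_cpp(int x1, int n1, int x2, int n2, NumericVector grid) {
  if (n1 <= 0 || n2 <= 0) stop("both row margins must be positive");
  double obs = fisher_one_sided(x1, n1, x2, n2);
  double thr = obs + obs * 1e-9 + 1e-12;

  std::vector<int> J(n1 + 1, -1);
  for (int i = 0; i <= n1; ++i) {
    if (fisher_one_sided(i, n1, 0, n2) > thr) continue;
    int lo = 0, hi = n2;
    while (lo < hi) {
      int mid = lo + (hi - lo + 1) / 2;
      if (fisher_one_sided(i, n1, mid, n2) <= thr) lo = mid; else hi = mid - 1;
    }
    J[i] = lo;
  }

  std::vector<double> lc1(n1 + 1), lc2(n2 + 1);
  for (int i = 0; i <= n1; ++i) lc1[i] = R::lchoose((double)n1, (double)i);
  for (int j = 0; j <= n2; ++j) lc2[j] = R::lchoose((double)n2, (double)j);

  std::vector<double> cum2(n2 + 1), d1(n1 + 1);
  double best = 0.0;
  for (R_xlen_t g = 0; g < grid.size(); ++g) {
    double pi = grid[g];
    if (!(pi > 0.0 && pi < 1.0)) continue;
    double lp = std::log(pi), lq = std::log1p(-pi);
    double c = 0.0;
    for (int j = 0; j <= n2; ++j) {
      c += std::exp(lc2[j] + j * lp + (n2 - j) * lq);
      cum2[j] = c;
    }
    double s = 0.0;
    for (int i = 0; i <= n1; ++i) {
      if (J[i] >= 0)
        s += std::exp(lc1[i] + i * lp + (n1 - i) * lq) * cum2[J[i]];
    }
    if (s > best) best = s;
  }
  if (best > 1.0) best = 1.0;
  if (best <= 0.0) best = std::numeric_limits<double>::min();
  return best;
}
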