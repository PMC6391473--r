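#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo exceedance count for the difference-of-means permutation test.
// Each permutation redistributes the pooled values into bins of the original
// sizes without replacement (partial Fisher-Yates driven by R's RNG, so
// set.seed() in R makes the count reproducible).
// [[Rcpp::export(name = ".perm_exceed_count")]]
int perm_exceed_count(NumericVector pooled, int n_control, int n_permutations,
                      double threshold, bool two_sided) {
  const int n = pooled.size();
  const int n_e = n - n_control;
  const double tot = sum(pooled);
  std::vector<double> x(pooled.begin(), pooled.end());
  int exceed = 0;
  for (int b = 0; b < n_permutations; ++b) {
    double s = 0.0;
    for (int i = 0; i < n_control; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(x[i], x[j]);
      s += x[i];
    }
    double d = s / n_control - (tot - s) / n_e;
    if (two_sided) d = std::abs(d);
    if (d >= threshold) ++exceed;
  }
  return exceed;
}
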