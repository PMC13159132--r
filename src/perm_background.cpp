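#include <Rcpp.h>
using namespace Rcpp;

// Permutation background for one cell: n_perm means of k expression values
// sampled uniformly without replacement from x. Uses R's RNG stream, so
// results are reproducible under set.seed(). Partial Fisher-Yates per draw;
// the index pool stays shuffled between draws, which preserves uniformity.
// [[Rcpp::export]]
NumericVector perm_background_means(NumericVector x, int k, int n_perm) {
  const int g = x.size();
  if (k < 1) stop("k must be >= 1");
  if (k > g) stop("k (%d) exceeds the number of genes (%d)", k, g);
  if (n_perm < 1) stop("n_perm must be >= 1");
  std::vector<int> idx(g);
  for (int i = 0; i < g; ++i) idx[i] = i;
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) {
      int rest = g - j;
      int r = j + (int)(unif_rand() * rest);
      if (r >= g) r = g - 1;  // guard against unif_rand() == 1.0
      std::swap(idx[j], idx[r]);
      s += x[idx[j]];
    }
    out[p] = s / k;
  }
  return out;
}

// Matrix-level scoring: for every cell (row of values), the observed mean
// over the marker columns, the mean of n_perm random k-subset means, and
// the count of background means strictly above the observed mean.
// idx is 1-based. Same sampling scheme as perm_background_means.
// [[Rcpp::export]]
NumericMatrix score_marker_set(NumericMatrix values, IntegerVector idx,
                               int n_perm) {
  const int n = values.nrow(), g = values.ncol(), k = idx.size();
  if (k < 1 || k > g) stop("marker set size out of range");
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("observed", "bg_mean", "n_exceed");
  std::vector<int> pool(g);
  for (int i = 0; i < g; ++i) pool[i] = i;
  std::vector<double> x(g);
  for (int c = 0; c < n; ++c) {
    for (int j = 0; j < g; ++j) x[j] = values(c, j);
    double obs = 0.0;
    for (int j = 0; j < k; ++j) obs += x[idx[j] - 1];
    obs /= k;
    double bgsum = 0.0;
    int exceed = 0;
    for (int p = 0; p < n_perm; ++p) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        int rest = g - j;
        int r = j + (int)(unif_rand() * rest);
        if (r >= g) r = g - 1;
        std::swap(pool[j], pool[r]);
        s += x[pool[j]];
      }
      s /= k;
      bgsum += s;
      if (s > obs) ++exceed;
    }
    out(c, 0) = obs;
    out(c, 1) = bgsum / n_perm;
    out(c, 2) = exceed;
  }
  return out;
}
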