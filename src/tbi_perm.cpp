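#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle of one column using R's RNG stream, so results are
// reproducible under set.seed().
static void shuffle_col(std::vector<int>& v) {
  const int n = static_cast<int>(v.size());
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i; // guard against unif_rand() == 1.0
    std::swap(v[i], v[j]);
  }
}

// Permutation kernel for the per-site temporal beta-diversity test under
// the independent-column-permutation null: each species column is permuted
// across sites, separately in each period's matrix, and every site's
// Sorensen dissimilarity D = (b + c) / (2a + b + c) is recomputed each
// round. Returns, per site, the number of permutations whose D is >= the
// observed D (ties count; permuted D undefined when 2a+b+c = 0 never
// counts).
// [[Rcpp::export]]
IntegerVector tbi_perm_exceed(const IntegerMatrix& t1,
                              const IntegerMatrix& t2,
                              const NumericVector& d_obs,
                              const int n_perm) {
  const int n = t1.nrow(), p = t1.ncol();
  std::vector<std::vector<int> > c1(p, std::vector<int>(n));
  std::vector<std::vector<int> > c2(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      c1[j][i] = t1(i, j);
      c2[j][i] = t2(i, j);
    }

  IntegerVector exceed(n);
  for (int k = 0; k < n_perm; ++k) {
    for (int j = 0; j < p; ++j) {
      shuffle_col(c1[j]);
      shuffle_col(c2[j]);
    }
    for (int i = 0; i < n; ++i) {
      if (NumericVector::is_na(d_obs[i])) continue;
      int a = 0, b = 0, c = 0;
      for (int j = 0; j < p; ++j) {
        const int x = c1[j][i], y = c2[j][i];
        if (x == 1 && y == 1) ++a;
        else if (x == 1) ++b;
        else if (y == 1) ++c;
      }
      const int denom = 2 * a + b + c;
      if (denom == 0) continue;
      const double d = static_cast<double>(b + c) / denom;
      if (d >= d_obs[i]) ++exceed[i];
    }
  }
  return exceed;
}
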