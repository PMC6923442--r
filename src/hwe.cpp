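#include <Rcpp.h>
using namespace Rcpp;

// Conditional Monte-Carlo exact test of Hardy-Weinberg proportions.
//
// Given the multiset of 2n gene copies at a locus, the HWE conditional
// distribution of the genotype table given the allele counts is exactly
// the distribution induced by pairing the copies uniformly at random.
// Each iteration draws an independent uniform pairing (Fisher-Yates
// shuffle of the copy vector, consecutive positions paired) and compares
// the conditional probability of the resulting table with the observed
// one; the P-value is the probability-ordering tail.  R's RNG is used,
// so results are reproducible under set.seed().
//
// The comparable part of log P(table | allele counts) is
//   h * log 2 - sum_{cells} lgamma(n_ij + 1)
// (h = number of heterozygotes); the remaining factors depend only on
// the allele counts.

static double table_score(const std::vector<int> &v, int k,
                          std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  int m = (int)v.size();
  int h = 0;
  for (int j = 0; j < m; j += 2) {
    int a = v[j], b = v[j + 1];
    if (a > b) std::swap(a, b);
    cnt[a * k + b]++;
    if (a != b) h++;
  }
  double s = h * M_LN2;
  for (int c : cnt)
    if (c > 1) s -= R::lgammafn(c + 1.0);
  return s;
}

// [[Rcpp::export(name = ".hwe_shuffle_mc_cpp")]]
List hwe_shuffle_mc_cpp(IntegerVector alleles, int k, int B) {
  std::vector<int> v(alleles.begin(), alleles.end());
  int m = (int)v.size();
  std::vector<int> cnt(k * k, 0);
  double obs = table_score(v, k, cnt);
  int n_le = 0;
  for (int b = 0; b < B; b++) {
    for (int j = m - 1; j > 0; j--) {
      int r = (int)(unif_rand() * (j + 1));
      if (r > j) r = j;
      std::swap(v[j], v[r]);
    }
    double s = table_score(v, k, cnt);
    if (s <= obs + 1e-9) n_le++;
  }
  return List::create(_["n_le"] = n_le, _["score_obs"] = obs);
}
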