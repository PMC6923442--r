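#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Fast ABC summary statistics on raw allele matrices.
// Layout matches the R front-end: per deme (na, hexp, vsize, gw), then
// per pair (i<j, row-major) (theta_WC, shared-allele distance, dmu2).
// Missing calls are NA in a1/a2.

// [[Rcpp::export(name = ".sumstats_cpp")]]
NumericVector sumstats_cpp(IntegerMatrix a1, IntegerMatrix a2,
                           IntegerVector deme, int D) {
  const int n = a1.nrow(), L = a1.ncol();
  const int P = D * (D - 1) / 2;
  NumericVector out(4 * D + 3 * P);

  // per-deme per-locus allele counts
  std::vector<std::vector<std::map<int, int>>> cnt(
      D, std::vector<std::map<int, int>>(L));
  std::vector<std::vector<int>> nobs(D, std::vector<int>(L, 0));
  std::vector<std::vector<std::map<int, int>>> hetc(
      D, std::vector<std::map<int, int>>(L));   // het carriers per allele
  for (int i = 0; i < n; ++i) {
    int d = deme[i] - 1;
    for (int l = 0; l < L; ++l) {
      if (a1(i, l) == NA_INTEGER) continue;
      cnt[d][l][a1(i, l)]++;
      cnt[d][l][a2(i, l)]++;
      nobs[d][l]++;
      if (a1(i, l) != a2(i, l)) {
        hetc[d][l][a1(i, l)]++;
        hetc[d][l][a2(i, l)]++;
      }
    }
  }

  // per-deme statistics
  std::vector<std::vector<double>> mean_size(D, std::vector<double>(L, 0.0));
  for (int d = 0; d < D; ++d) {
    double sna = 0, shx = 0, svs = 0, sgw = 0;
    for (int l = 0; l < L; ++l) {
      const auto &c = cnt[d][l];
      double n2 = 2.0 * nobs[d][l];
      int k = (int)c.size();
      double sum = 0, sumsq = 0, sump2 = 0;
      int amin = 0, amax = 0; bool first = true;
      for (auto &kv : c) {
        double p = kv.second / n2;
        sump2 += p * p;
        sum += (double)kv.first * kv.second;
        sumsq += (double)kv.first * kv.first * kv.second;
        if (first) { amin = amax = kv.first; first = false; }
        else { amin = std::min(amin, kv.first); amax = std::max(amax, kv.first); }
      }
      double m = sum / n2;
      mean_size[d][l] = m;
      double vs = (n2 > 1) ? (sumsq - n2 * m * m) / (n2 - 1) : 0.0;
      double hx = (n2 > 1) ? (n2 / (n2 - 1)) * (1.0 - sump2) : 0.0;
      sna += k;
      shx += hx;
      svs += vs;
      sgw += k / ((double)(amax - amin) + 1.0);
    }
    out[4 * d] = sna / L;
    out[4 * d + 1] = shx / L;
    out[4 * d + 2] = svs / L;
    out[4 * d + 3] = sgw / L;
  }

  // pairwise statistics
  int pos = 4 * D;
  for (int di = 0; di < D - 1; ++di) {
    for (int dj = di + 1; dj < D; ++dj) {
      double num = 0, den = 0, das = 0, dmu = 0;
      for (int l = 0; l < L; ++l) {
        double ni = nobs[di][l], nj = nobs[dj][l];
        // shared-allele distance and dmu2
        double shared = 0;
        for (auto &kv : cnt[di][l]) {
          auto it = cnt[dj][l].find(kv.first);
          if (it != cnt[dj][l].end())
            shared += std::min(kv.second / (2.0 * ni),
                               it->second / (2.0 * nj));
        }
        das += 1.0 - shared;
        double dm = mean_size[di][l] - mean_size[dj][l];
        dmu += dm * dm;
        // Weir-Cockerham components (r = 2)
        std::map<int, int> all;
        for (auto &kv : cnt[di][l]) all[kv.first] = 1;
        for (auto &kv : cnt[dj][l]) all[kv.first] = 1;
        if (all.size() < 2 || ni == 0 || nj == 0) continue;
        double r = 2.0, nbar = (ni + nj) / 2.0;
        if (nbar <= 1) continue;
        double nc = (r * nbar - (ni * ni + nj * nj) / (r * nbar)) / (r - 1);
        if (nc <= 0) continue;
        for (auto &kv : all) {
          int a = kv.first;
          auto gi = cnt[di][l].find(a), gj = cnt[dj][l].find(a);
          double pi = (gi == cnt[di][l].end()) ? 0 : gi->second / (2.0 * ni);
          double pj = (gj == cnt[dj][l].end()) ? 0 : gj->second / (2.0 * nj);
          auto hi = hetc[di][l].find(a), hj = hetc[dj][l].find(a);
          double h_i = (hi == hetc[di][l].end()) ? 0 : hi->second / ni;
          double h_j = (hj == hetc[dj][l].end()) ? 0 : hj->second / nj;
          double pbar = (ni * pi + nj * pj) / (r * nbar);
          double s2 = (ni * (pi - pbar) * (pi - pbar) +
                       nj * (pj - pbar) * (pj - pbar)) / ((r - 1) * nbar);
          double hbar = (ni * h_i + nj * h_j) / (r * nbar);
          double aa = nbar / nc *
            (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                    (nbar - 1));
          double bb = nbar / (nbar - 1) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar);
          double cc = hbar / 2;
          num += aa;
          den += aa + bb + cc;
        }
      }
      out[pos++] = (den > 0) ? num / den : 0.0;
      out[pos++] = das / L;
      out[pos++] = dmu / L;
    }
  }
  return out;
}
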