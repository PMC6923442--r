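#include <Rcpp.h>
using namespace Rcpp;

// Coalescent simulator for microsatellite loci under a piecewise-constant
// multi-deme demography with founding events (backwards-in-time lineage
// transfers) and the generalized stepwise mutation model.
//
// Demography encoding (all times in generations, backwards from 0):
//  - sizes: matrix with rows (deme, t_start, N): diploid effective size of
//    `deme` from t_start until the next larger t_start for that deme.
//    Coalescence rate for k lineages in a deme of size N is
//    k(k-1)/2 * 1/(2N) per generation (continuous-time within epochs).
//  - merges: matrix with rows (time, from, to), ascending in time: at
//    `time` all lineages of deme `from` move to deme `to`.
//  - samples: diploids sampled per deme at time 0.
// Mutation: per locus rate mu (expected mutations per generation per
// lineage); each mutation shifts the repeat number by +/- s where
// s = 1 + Geometric(gsm_p) (gsm_p = 0 gives the strict stepwise model);
// resulting alleles are clamped to [amin, amax].  Root allele = root.
// All randomness from R's RNG (set.seed-reproducible).

static int gsm_step(double gsm_p) {
  int s = 1;
  if (gsm_p > 0.0) {
    double u = unif_rand();
    s = 1 + (int)std::floor(std::log(u) / std::log(gsm_p));
    if (s < 1) s = 1;
    if (s > 1000) s = 1000;
  }
  return (unif_rand() < 0.5) ? -s : s;
}

// [[Rcpp::export(name = ".coalsim_cpp")]]
IntegerMatrix coalsim_cpp(IntegerVector samples, NumericMatrix sizes,
                          NumericMatrix merges, NumericVector mu,
                          double gsm_p, int root, int amin, int amax) {
  const int D = samples.size();
  const int L = mu.size();
  int n_tot = 0;
  for (int d = 0; d < D; ++d) n_tot += samples[d];
  const int n_genes = 2 * n_tot;
  IntegerMatrix out(n_tot, 2 * L);

  // per-deme size lookup
  std::vector<std::vector<std::pair<double, double>>> seg(D);
  for (int r = 0; r < sizes.nrow(); ++r)
    seg[(int)sizes(r, 0)].push_back({sizes(r, 1), sizes(r, 2)});
  for (int d = 0; d < D; ++d)
    std::sort(seg[d].begin(), seg[d].end());
  auto size_at = [&](int d, double t) -> double {
    double N = seg[d].empty() ? 1.0 : seg[d][0].second;
    for (auto &s : seg[d]) { if (s.first <= t + 1e-12) N = s.second; else break; }
    return std::max(N, 0.5);
  };

  // structural breakpoints: merge times and segment starts
  std::vector<double> breaks;
  for (int r = 0; r < merges.nrow(); ++r) breaks.push_back(merges(r, 0));
  for (int d = 0; d < D; ++d)
    for (auto &s : seg[d]) if (s.first > 0) breaks.push_back(s.first);
  std::sort(breaks.begin(), breaks.end());

  const int max_nodes = 2 * n_genes;
  std::vector<int> parent(max_nodes), deme_of_leaf(n_genes);
  std::vector<double> ntime(max_nodes);
  {
    int g = 0;
    for (int d = 0; d < D; ++d)
      for (int i = 0; i < 2 * samples[d]; ++i) deme_of_leaf[g++] = d;
  }

  std::vector<int> active;      // node ids
  std::vector<int> ademe;       // deme per active lineage

  for (int l = 0; l < L; ++l) {
    // init
    active.resize(n_genes); ademe.resize(n_genes);
    for (int g = 0; g < n_genes; ++g) {
      active[g] = g; ademe[g] = deme_of_leaf[g];
      parent[g] = -1; ntime[g] = 0.0;
    }
    int next_node = n_genes;
    double t = 0.0;
    size_t mi = 0, bi = 0;
    // a deme that has merged away redirects later arrivals to its
    // destination (handles simultaneous/chained founding events)
    std::vector<int> redirect(D);
    for (int d = 0; d < D; ++d) redirect[d] = d;
    auto resolve = [&](int d) {
      int guard = 0;
      while (redirect[d] != d && guard++ < D + 1) d = redirect[d];
      return d;
    };
    while ((int)active.size() > 1) {
      // next structural breakpoint
      double t_next = R_PosInf;
      while (bi < breaks.size() && breaks[bi] <= t + 1e-12) ++bi;
      if (bi < breaks.size()) t_next = breaks[bi];
      // candidate coalescence: minimum over demes
      double t_min = R_PosInf;
      int d_min = -1;
      std::vector<int> kcount(D, 0);
      for (size_t i = 0; i < active.size(); ++i) kcount[ademe[i]]++;
      for (int d = 0; d < D; ++d) {
        int k = kcount[d];
        if (k < 2) continue;
        double N = size_at(d, t);
        double rate = k * (k - 1.0) / 2.0 / (2.0 * N);
        double dt = exp_rand() / rate;
        if (t + dt < t_min) { t_min = t + dt; d_min = d; }
      }
      if (t_min < t_next) {
        // coalesce two random lineages in deme d_min
        std::vector<int> in_d;
        for (size_t i = 0; i < active.size(); ++i)
          if (ademe[i] == d_min) in_d.push_back(i);
        int i1 = in_d[(int)(unif_rand() * in_d.size()) % in_d.size()];
        int i2;
        do {
          i2 = in_d[(int)(unif_rand() * in_d.size()) % in_d.size()];
        } while (i2 == i1);
        int node = next_node++;
        ntime[node] = t_min; parent[node] = -1;
        parent[active[i1]] = node;
        parent[active[i2]] = node;
        int lo = std::min(i1, i2), hi = std::max(i1, i2);
        active[lo] = node;
        active.erase(active.begin() + hi);
        ademe.erase(ademe.begin() + hi);
        t = t_min;
      } else {
        if (!std::isfinite(t_next)) {
          // should not happen: all merges exhausted but >1 lineage and
          // no coalescing deme (guarded by scenario validation)
          stop("coalescent stalled: lineages cannot reach a common deme");
        }
        t = t_next;
        // apply any merges at exactly this time
        while (mi < (size_t)merges.nrow() &&
               merges(mi, 0) <= t + 1e-12) {
          int from = (int)merges(mi, 1);
          int to = resolve((int)merges(mi, 2));
          for (size_t i = 0; i < ademe.size(); ++i)
            if (ademe[i] == from) ademe[i] = to;
          redirect[from] = to;
          ++mi;
        }
      }
    }
    // mutations down the tree
    int root_node = active[0];
    std::vector<int> allele(next_node);
    allele[root_node] = root;
    // process nodes in decreasing time order (parents before children):
    // node ids are created in time order, so iterate descending ids,
    // assigning children from their parents
    for (int node = next_node - 1; node >= 0; --node) {
      if (node == root_node) continue;
      int par = parent[node];
      double len = ntime[par] - ntime[node];
      int nm = (int)R::rpois(mu[l] * len);
      int a = allele[par];
      for (int m = 0; m < nm; ++m) a += gsm_step(gsm_p);
      if (a < amin) a = amin;
      if (a > amax) a = amax;
      allele[node] = a;
    }
    for (int i = 0; i < n_tot; ++i) {
      int a1 = allele[2 * i], a2 = allele[2 * i + 1];
      out(i, 2 * l) = std::min(a1, a2);
      out(i, 2 * l + 1) = std::max(a1, a2);
    }
  }
  return out;
}
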