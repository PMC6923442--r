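#include <Rcpp.h>
using namespace Rcpp;

// Bayesian admixture (STRUCTURE-style) Gibbs sampler with correlated
// allele frequencies.
//
// Model: each of the 2 allele copies of individual i at locus l has a
// latent cluster origin z ~ Categorical(q_i); allele | z = k drawn from
// the cluster frequencies p_{k,l,.}.  Priors: q_i ~ Dirichlet(alpha)
// with a single alpha shared across individuals (uniform(0,10)
// hyperprior, Metropolis update); p_{k,l,.} ~ Dirichlet(pbar_l *
// (1-F_k)/F_k) anchored at the empirical mean frequencies pbar (the
// correlated-frequency F-model), with per-cluster drift F_k ~
// uniform(0,1) updated by Metropolis.  Missing calls are skipped.
// All randomness comes from R's RNG, so runs are reproducible under
// set.seed().
//
// geno: n x 2L matrix of 0-based allele indices, -1 = missing
// n_alleles: number of alleles per locus

static double rgamma_pos(double shape) {
  double x = R::rgamma(shape, 1.0);
  return (x > 1e-300) ? x : 1e-300;
}

static void rdirichlet_into(const std::vector<double> &alpha,
                            std::vector<double> &out) {
  double s = 0.0;
  for (size_t a = 0; a < alpha.size(); ++a) {
    out[a] = rgamma_pos(alpha[a]);
    s += out[a];
  }
  for (size_t a = 0; a < alpha.size(); ++a) out[a] /= s;
}

static double ddirichlet_log(const std::vector<double> &x,
                             const std::vector<double> &alpha) {
  double s = 0.0, lg = 0.0, ll = 0.0;
  for (size_t a = 0; a < alpha.size(); ++a) {
    s += alpha[a];
    lg += R::lgammafn(alpha[a]);
    ll += (alpha[a] - 1.0) * std::log(x[a]);
  }
  return R::lgammafn(s) - lg + ll;
}

// [[Rcpp::export(name = ".structure_gibbs_cpp")]]
List structure_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int burnin, int iters, int thin,
                         double alpha_init, double alpha_max,
                         double alpha_step, double f_step) {
  const int n = geno.nrow();
  const int L = n_alleles.size();

  // empirical mean frequencies (add-one smoothing over observed alleles)
  std::vector<std::vector<double>> pbar(L);
  for (int l = 0; l < L; ++l) {
    pbar[l].assign(n_alleles[l], 1.0);
    double tot = n_alleles[l];
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = geno(i, 2 * l + c);
        if (a >= 0) { pbar[l][a] += 1.0; tot += 1.0; }
      }
    for (int a = 0; a < n_alleles[l]; ++a) pbar[l][a] /= tot;
  }

  // state
  std::vector<std::vector<std::vector<double>>> p(K);
  for (int k = 0; k < K; ++k) {
    p[k].resize(L);
    for (int l = 0; l < L; ++l) p[k][l] = pbar[l];
  }
  std::vector<double> q(n * K, 1.0 / K);
  std::vector<int> z(n * 2 * L, 0);
  std::vector<double> Fk(K, 0.1);
  double alpha = alpha_init;

  // initialize z uniformly
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c)
        z[(i * L + l) * 2 + c] = (int)(unif_rand() * K) % K;

  std::vector<double> qsum(n * K, 0.0);
  std::vector<std::vector<std::vector<double>>> psum(K);
  for (int k = 0; k < K; ++k) {
    psum[k].resize(L);
    for (int l = 0; l < L; ++l) psum[k][l].assign(n_alleles[l], 0.0);
  }
  int n_samples = 0;
  std::vector<double> ll_trace, alpha_trace, f_trace;

  std::vector<double> prob(K), dir(64), tmp(64);
  std::vector<std::vector<double>> cnt(K);

  const int total = burnin + iters;
  for (int it = 0; it < total; ++it) {
    // --- z | q, p
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = q[i * K + k] * p[k][l][a];
            s += prob[k];
          }
          double u = unif_rand() * s, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { pick = k; break; }
          }
          z[(i * L + l) * 2 + c] = pick;
        }
      }
    }
    // --- q | z
    for (int i = 0; i < n; ++i) {
      std::vector<double> a(K, alpha);
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          if (geno(i, 2 * l + c) < 0) continue;
          a[z[(i * L + l) * 2 + c]] += 1.0;
        }
      if ((int)tmp.size() < K) tmp.resize(K);
      std::vector<double> qi(K);
      rdirichlet_into(a, qi);
      for (int k = 0; k < K; ++k) q[i * K + k] = qi[k];
    }
    // --- p | z  (F-model prior)
    for (int k = 0; k < K; ++k) {
      double lam = (1.0 - Fk[k]) / std::max(Fk[k], 1e-6);
      for (int l = 0; l < L; ++l) {
        int m = n_alleles[l];
        std::vector<double> a(m);
        for (int aa = 0; aa < m; ++aa) a[aa] = pbar[l][aa] * lam;
        for (int i = 0; i < n; ++i)
          for (int c = 0; c < 2; ++c) {
            int al = geno(i, 2 * l + c);
            if (al < 0) continue;
            if (z[(i * L + l) * 2 + c] == k) a[al] += 1.0;
          }
        rdirichlet_into(a, p[k][l]);
      }
    }
    // --- F_k Metropolis
    for (int k = 0; k < K; ++k) {
      double fprop = Fk[k] + norm_rand() * f_step;
      while (fprop < 1e-4 || fprop > 1.0 - 1e-4) {
        if (fprop < 1e-4) fprop = 2e-4 - fprop;
        if (fprop > 1.0 - 1e-4) fprop = 2.0 * (1.0 - 1e-4) - fprop;
      }
      double lam_old = (1.0 - Fk[k]) / Fk[k];
      double lam_new = (1.0 - fprop) / fprop;
      double lr = 0.0;
      std::vector<double> ao, an;
      for (int l = 0; l < L; ++l) {
        int m = n_alleles[l];
        ao.assign(m, 0.0); an.assign(m, 0.0);
        for (int aa = 0; aa < m; ++aa) {
          ao[aa] = pbar[l][aa] * lam_old;
          an[aa] = pbar[l][aa] * lam_new;
        }
        lr += ddirichlet_log(p[k][l], an) - ddirichlet_log(p[k][l], ao);
      }
      if (std::log(unif_rand()) < lr) Fk[k] = fprop;
    }
    // --- alpha Metropolis (skip for K = 1)
    if (K > 1) {
      double aprop = alpha + norm_rand() * alpha_step;
      if (aprop > 1e-4 && aprop < alpha_max) {
        double sumlogq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            sumlogq += std::log(std::max(q[i * K + k], 1e-300));
        double lr =
          n * (R::lgammafn(K * aprop) - K * R::lgammafn(aprop)) +
          (aprop - 1.0) * sumlogq -
          (n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
           (alpha - 1.0) * sumlogq);
        if (std::log(unif_rand()) < lr) alpha = aprop;
      }
    }
    // --- record
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += q[i * K + k] * p[k][l][a];
            ll += std::log(std::max(s, 1e-300));
          }
      ll_trace.push_back(ll);
      alpha_trace.push_back(alpha);
      double fm = 0.0;
      for (int k = 0; k < K; ++k) fm += Fk[k];
      f_trace.push_back(fm / K);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum[i * K + k] += q[i * K + k];
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < n_alleles[l]; ++a)
            psum[k][l][a] += p[k][l][a];
      ++n_samples;
    }
  }

  NumericMatrix qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      qmean(i, k) = qsum[i * K + k] / n_samples;
  List pmean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pl(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a)
        pl(k, a) = psum[k][l][a] / n_samples;
    pmean[l] = pl;
  }
  return List::create(
    _["q"] = qmean, _["p"] = pmean,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["alpha_trace"] = NumericVector(alpha_trace.begin(), alpha_trace.end()),
    _["f_trace"] = NumericVector(f_trace.begin(), f_trace.end()),
    _["n_samples"] = n_samples);
}
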