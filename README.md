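# outbreakgen

Population-genetic analysis of invasive insect outbreaks from nuclear
microsatellite (SSR) genotypes.

When a quarantine pest such as a wood-boring beetle is discovered, the
infested trees are sampled and destroyed; what remains is a set of
diploid multilocus genotypes from a few small, recently founded
populations.  `outbreakgen` turns those genotypes into the standard
fine-scale invasion-genetics analysis:

* **Data model and QC** — GenePop, STRUCTURE and delimited-table
  input/output; removal of specimens with more than 10% missing loci
  and of monomorphic loci; unique multilocus genotype (uMLG) counting
  with explicit missing-data rules.
* **Diversity and differentiation** — per-population allele richness
  (Na), private alleles (Pa), Nei's unbiased gene diversity
  (H<sub>exp</sub>), observed heterozygosity, E5 genotype evenness, and
  the Weir–Cockerham fixation index *f* (F<sub>IS</sub>) with
  permutation P-values; exact Hardy–Weinberg tests (full enumeration or
  conditional Monte Carlo); permutation G-tests of linkage
  disequilibrium with Holm correction; pairwise multilocus
  Weir–Cockerham θ (F<sub>ST</sub>) with permutation significance,

  θ = Σ<sub>loci,alleles</sub> a / Σ<sub>loci,alleles</sub> (a + b + c),

  the ratio of summed among-population variance components to summed
  totals.
* **DAPC** — discriminant analysis of principal components with
  leakage-free cross-validated choice of the retained PCs and posterior
  assignment of specimens to their origin groups.
* **Admixture clustering** — a Gibbs sampler for the admixture model
  with correlated allele frequencies (F-model), ln P(X|K) estimation,
  Evanno ΔK over a K grid, and greedy cross-run label alignment.
* **Demographic reconstruction (ABC)** — a coalescent simulator for
  microsatellites under piecewise-constant deme sizes, founder
  bottlenecks and founding events, with generalized stepwise mutation;
  reference tables of summary statistics; scenario choice by the direct
  (closest-500) and LDA + multinomial-logistic routes; local-linear
  parameter estimation; scenario-confidence (type I/II) calibration and
  posterior-predictive goodness-of-fit.
* **Synthetic data** — seed-deterministic generators with truth
  records, including a "paper-like" preset that reconstructs a full
  four-outbreak survey (223 specimens, 15 loci) by design.

The methods vignette
(`vignettes/outbreak-genetics-methods.Rmd`) documents every model,
default and numerical choice.

## Worked example

```r
library(outbreakgen)

# a synthetic four-outbreak survey with planted structure
survey <- make_paperlike_dataset(seed = 1)
qc <- qc_dataset(survey$dataset)
qc$report$n_specimens_retained   # 192 (of 223; 31 removed at >10% missing)
qc$report$n_loci_retained        # 13  (of 15; 2 monomorphic dropped)

d <- qc$dataset
summarize_population(d, "Berikon", n_permutations = 199)
#> Berikon: n=20 uMLG=13 Na=2.08+/-0.86 Pa=1 Hexp=0.36 Hobs=0.25
#>   Fis=0.33 (P=0.005) E5=0.69

pairwise_fst(d, "Marly", "Bruenisried", n_permutations = 199)
#> F_ST(Marly, Bruenisried) = 0.07  (P = 0.005, 199 permutations)

# the Marly spots and Bruenisried as demes for the ABC reconstruction
md <- marly_demes(d)
pairwise_fst(md, "Ma1", "Ma2", n_permutations = 0)$theta   # 0.118
pairwise_fst(md, "Ma1", "Br",  n_permutations = 0)$theta   # 0.082

# admixture clustering over K = 1..6 with Evanno diagnostics
ks <- structure_kscan(d, k_values = 1:6, n_runs = 3, seed = 7,
                      burnin = 2000, iters = 4000)
attr(ks$evanno, "best_k")

# scenario choice for the history linking the three demes
scenarios <- default_scenarios()        # SC1..SC6 in the scenario DSL
priors <- default_priors(step2 = TRUE)  # first arrival <= 10 generations
tab <- build_reference_table(scenarios[c("SC6", "SC5")], priors,
                             n_per_scenario = 10000,
                             sample_config = c(Ma1 = 34, Ma2 = 14, Br = 53),
                             n_loci = 13, seed = 17)
obs <- compute_sumstats(md, c("Ma1", "Ma2", "Br"))
select_scenario_lda_logistic(obs, tab)  # posterior probability per scenario
```

The numbers shown are what the code prints for `seed = 1`: the QC
counts and diversity values are planted by the preset's design (and are
seed-invariant for retained specimens), so they double as a pipeline
self-check.

An end-to-end run with consolidated outputs (CSV tables, JSON machine
reports, a manifest with seeds and runtimes):

```r
cfg <- pipeline_config(input = list(synthetic = "paperlike"),
                       output_dir = "results", seed = 1)
run_pipeline(cfg)
```

A thin command-line wrapper ships in `inst/exec/outbreak-genetics`
(subcommands `run`, `synth`, `qc`).

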