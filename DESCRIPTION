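Package: outbreakgen
Title: Fine-Scale Invasion Genetics of Insect Outbreaks from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genetic analysis of invasive insect outbreaks
    genotyped at nuclear microsatellite (SSR) loci.  Provides a genotype
    data model with GenePop, STRUCTURE and delimited-table input/output
    and quality-control filters; per-population diversity summaries
    (allelic richness, private alleles, unbiased gene diversity,
    multilocus-genotype evenness), exact Hardy-Weinberg and linkage
    disequilibrium tests, and pairwise Weir-Cockerham F_ST with
    permutation significance; discriminant analysis of principal
    components (DAPC); a Bayesian admixture (STRUCTURE-style) Gibbs
    sampler with correlated allele frequencies, Evanno Delta-K model
    selection and greedy cross-run label alignment; and a coalescent
    microsatellite simulator under the generalized stepwise mutation
    model coupled to approximate Bayesian computation for demographic
    scenario choice and parameter estimation.  A synthetic-data module
    generates datasets with the statistical structure of real outbreak
    data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    nnet,
    Rcpp,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
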