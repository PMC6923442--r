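#' Configuration for the admixed synthetic genotype generator
#'
#' Defaults describe a small multi-population SSR survey: a handful of
#' strongly drifted clusters, one specimen population per cluster,
#' moderate inbreeding, and host-tree clustering of genotypes (each tree
#' draws a dominant cluster; specimens on it usually belong to that
#' cluster).
#'
#' @param n_clusters number of latent genetic clusters.
#' @param pop_sizes named integer vector of specimens per population;
#'   populations map to clusters round-robin.
#' @param n_loci number of SSR loci.
#' @param n_alleles alleles per locus (scalar or per-locus vector).
#' @param drift cluster drift from the shared ancestral pool in (0, 1);
#'   approximately the expected among-cluster F_ST.
#' @param admixture_alpha symmetric Dirichlet admixture noise.
#' @param purity extra Dirichlet weight on the specimen's own cluster.
#' @param inbreeding probability that a call is homozygous by descent
#'   (realized F_IS approximates this).
#' @param missing_rate fraction of calls masked missing, uniformly.
#' @param trees_per_pop number of host trees per population (0 = no tree
#'   structure).
#' @param tree_fidelity probability that a specimen belongs to its tree's
#'   dominant cluster.
#' @param seed RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_clusters = 3, pop_sizes = NULL, n_loci = 12,
                         n_alleles = 5, drift = 0.3,
                         admixture_alpha = 0.1, purity = 10,
                         inbreeding = 0.0, missing_rate = 0.0,
                         trees_per_pop = 0, tree_fidelity = 0.9,
                         seed = 1L) {
  if (is.null(pop_sizes)) {
    pop_sizes <- rep(30L, n_clusters)
    names(pop_sizes) <- paste0("pop", seq_len(n_clusters))
  }
  stopifnot(all(pop_sizes > 0), drift > 0, drift < 1,
            inbreeding >= 0, inbreeding <= 1,
            missing_rate >= 0, missing_rate < 1)
  n_alleles <- rep(n_alleles, length.out = n_loci)
  if (all(n_alleles <= 1)) stop("need at least one polymorphic locus")
  structure(list(n_clusters = n_clusters, pop_sizes = pop_sizes,
                 n_loci = n_loci, n_alleles = n_alleles, drift = drift,
                 admixture_alpha = admixture_alpha, purity = purity,
                 inbreeding = inbreeding, missing_rate = missing_rate,
                 trees_per_pop = trees_per_pop,
                 tree_fidelity = tree_fidelity, seed = seed),
            class = "synth_config")
}

#' Generate an admixed multi-population genotype dataset with known truth
#'
#' Cluster allele frequencies are drawn from a hierarchical Dirichlet
#' (F-model-like) prior around a shared ancestral pool; each specimen
#' receives admixture proportions concentrated on its population's
#' cluster; genotypes are drawn with the configured homozygosity excess;
#' calls are masked missing at the configured rate.  The truth record
#' carries everything needed for recovery scoring.
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (cluster frequencies `p` (cluster x locus x allele list), admixture
#'   `q`, per-specimen base cluster, tree assignment, the config).
#' @export
make_admixed_dataset <- function(config) {
  cf <- config
  set.seed(cf$seed)
  K <- cf$n_clusters
  pops <- names(cf$pop_sizes)
  n <- sum(cf$pop_sizes)
  pop_of <- rep(pops, cf$pop_sizes)
  cluster_of_pop <- ((seq_along(pops) - 1L) %% K) + 1L
  names(cluster_of_pop) <- pops

  # cluster allele frequencies around a shared ancestral pool
  p <- vector("list", cf$n_loci)
  for (l in seq_len(cf$n_loci)) {
    m <- cf$n_alleles[l]
    anc <- .rdirichlet(rep(1.5, m))
    p[[l]] <- t(vapply(seq_len(K), function(k)
      .rdirichlet(anc * (1 - cf$drift) / cf$drift), numeric(m)))
  }

  # trees and per-specimen base cluster
  tree <- rep(NA_character_, n)
  base <- integer(n)
  for (j in seq_along(pops)) {
    rows <- which(pop_of == pops[j])
    ck <- cluster_of_pop[j]
    if (cf$trees_per_pop > 0) {
      tr <- sample(rep(seq_len(cf$trees_per_pop), length.out = length(rows)))
      tree[rows] <- paste0(pops[j], "_tree", tr)
      dom <- ifelse(runif(cf$trees_per_pop) < cf$tree_fidelity, ck,
                    sample(K, cf$trees_per_pop, TRUE))
      for (t in seq_len(cf$trees_per_pop)) {
        on_tree <- rows[tr == t]
        base[on_tree] <- ifelse(runif(length(on_tree)) < cf$tree_fidelity,
                                dom[t], sample(K, length(on_tree), TRUE))
      }
    } else {
      base[rows] <- ck
    }
  }

  qm <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- rep(cf$admixture_alpha, K)
    a[base[i]] <- a[base[i]] + cf$purity
    .rdirichlet(a)
  }))

  a1 <- matrix(NA_integer_, n, cf$n_loci)
  a2 <- a1
  state <- function(idx) 10L + 2L * (idx - 1L)   # repeat-number ladder
  for (i in seq_len(n)) for (l in seq_len(cf$n_loci)) {
    if (runif(1) < cf$inbreeding) {
      z <- sample(K, 1, prob = qm[i, ])
      a <- sample(cf$n_alleles[l], 1, prob = p[[l]][z, ])
      a1[i, l] <- a2[i, l] <- state(a)
    } else {
      z <- sample(K, 2, TRUE, prob = qm[i, ])
      aa <- c(sample(cf$n_alleles[l], 1, prob = p[[l]][z[1], ]),
              sample(cf$n_alleles[l], 1, prob = p[[l]][z[2], ]))
      a1[i, l] <- state(min(aa)); a2[i, l] <- state(max(aa))
    }
  }
  if (cf$missing_rate > 0) {
    mask <- matrix(runif(n * cf$n_loci) < cf$missing_rate, n)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  ds <- genotype_dataset(a1, a2, sprintf("syn%03d", seq_len(n)),
                         sprintf("SSR%02d", seq_len(cf$n_loci)),
                         data.frame(population = pop_of, tree = tree,
                                    stringsAsFactors = FALSE))
  list(dataset = ds,
       truth = list(q = qm, p = p, base_cluster = base, tree = tree,
                    inbreeding = cf$inbreeding, config = cf))
}
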