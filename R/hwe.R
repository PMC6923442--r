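#' Exact test of Hardy-Weinberg proportions at one locus
#'
#' Conditional exact test on the genotype table given the allele counts,
#' with probability-ordering (two-sided) tail.  For biallelic loci the
#' full conditional distribution is enumerated (the table is determined
#' by the heterozygote count), giving an exact P-value.  Otherwise a
#' Monte-Carlo version draws independent uniform pairings of the gene
#' copies — exact sampling from the conditional null, the same target as
#' the classic genotype-table switch chain — and reports the Monte-Carlo
#' P with its binomial standard error.
#'
#' @param ds a [genotype_dataset()].
#' @param population population name.
#' @param locus locus name.
#' @param chain_config list; `n_samples` Monte-Carlo draws
#'   (default 10000).
#' @param seed RNG seed (Monte-Carlo path).
#' @return list with `p_value`, `se` (0 for the enumerated path),
#'   `method` (`"enumeration"` or `"monte-carlo"`), `n_samples`, and
#'   `status` (`"ok"` or `"not testable"` for monomorphic loci; then
#'   `p_value` is `NA`).
#' @export
hwe_exact_test <- function(ds, population, locus,
                           chain_config = list(n_samples = 10000),
                           seed = 1L) {
  li <- match(locus, ds$loci)
  if (is.na(li)) stop("unknown locus: ", locus)
  idx <- .pop_idx(ds, population)
  x1 <- ds$a1[idx, li]; x2 <- ds$a2[idx, li]
  obs <- !is.na(x1)
  x1 <- x1[obs]; x2 <- x2[obs]
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2L)
    return(list(p_value = NA_real_, se = NA_real_, method = "none",
                n_samples = 0L, status = "not testable"))
  if (length(x1) < 3L)
    stop("need at least 3 observed individuals for the HWE test")
  if (length(alleles) == 2L) {
    p <- .hwe_enumerate_biallelic(x1, x2, alleles)
    return(list(p_value = p, se = 0, method = "enumeration",
                n_samples = NA_integer_, status = "ok"))
  }
  B <- chain_config$n_samples %||% 10000L
  copies <- as.vector(rbind(match(x1, alleles), match(x2, alleles))) - 1L
  set.seed(seed)
  res <- .hwe_shuffle_mc_cpp(as.integer(copies), length(alleles),
                             as.integer(B))
  p <- (res$n_le + 1) / (B + 1)
  list(p_value = p, se = sqrt(p * (1 - p) / B), method = "monte-carlo",
       n_samples = B, status = "ok")
}

# exact enumeration over heterozygote counts for 2 alleles
.hwe_enumerate_biallelic <- function(x1, x2, alleles) {
  n <- length(x1)
  nA <- sum(x1 == alleles[1]) + sum(x2 == alleles[1])
  nB <- 2L * n - nA
  h_obs <- sum(x1 != x2)
  hs <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logw <- vapply(hs, function(h) {
    h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((nB - h) / 2 + 1)
  }, numeric(1))
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  p_obs <- prob[hs == h_obs]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
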