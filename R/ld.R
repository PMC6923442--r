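#' Permutation G-test of linkage disequilibrium between two loci
#'
#' Builds the two-locus genotypic contingency table (individuals
#' classified by their unordered genotype at each locus) over individuals
#' observed at both loci, computes the log-likelihood-ratio statistic
#' `G = 2 * sum O * ln(O/E)`, and obtains its null distribution by
#' permuting one locus's genotypes among individuals.  The P-value uses
#' the add-one estimator and is therefore at least `1/(n_permutations+1)`.
#'
#' @param ds a [genotype_dataset()].
#' @param population population name.
#' @param locus_pair character vector of two locus names.
#' @param n_permutations permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `g`, `p_value`, `n_permutations`, `status` (`"ok"` or
#'   `"not testable"` when a locus is monomorphic within the population).
#' @export
ld_test <- function(ds, population, locus_pair, n_permutations = 1000,
                    seed = 1L) {
  stopifnot(length(locus_pair) == 2L)
  li <- match(locus_pair, ds$loci)
  if (anyNA(li)) stop("unknown locus in pair")
  idx <- .pop_idx(ds, population)
  gA <- paste(ds$a1[idx, li[1]], ds$a2[idx, li[1]])
  gB <- paste(ds$a1[idx, li[2]], ds$a2[idx, li[2]])
  obs <- !is.na(ds$a1[idx, li[1]]) & !is.na(ds$a1[idx, li[2]])
  gA <- gA[obs]; gB <- gB[obs]
  if (length(unique(gA)) < 2L || length(unique(gB)) < 2L)
    return(list(g = NA_real_, p_value = NA_real_,
                n_permutations = 0L, status = "not testable"))
  g_obs <- .g_stat(gA, gB)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations))
    if (.g_stat(gA, sample(gB)) >= g_obs - 1e-12) exceed <- exceed + 1L
  list(g = g_obs, p_value = (1 + exceed) / (n_permutations + 1),
       n_permutations = n_permutations, status = "ok")
}

.g_stat <- function(a, b) {
  tab <- table(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  O <- as.numeric(tab); E <- as.numeric(E)
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' Sorts the P-values ascending and compares the i-th smallest with
#' `alpha / (m - i + 1)`, stopping at the first failure; all later
#' P-values are non-significant.  Flags are monotone: if `p_i` is flagged
#' and `p_j < p_i` then `p_j` is flagged.
#'
#' @param p_values numeric vector of P-values in \[0, 1\].
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector of significance flags, in input order.
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(logical(0))
  stopifnot(all(is.finite(p_values)), all(p_values >= 0), all(p_values <= 1))
  ord <- order(p_values)
  flags <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) flags[ord[i]] <- TRUE
    else break
  }
  flags
}
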