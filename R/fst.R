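# Weir & Cockerham (1984) variance components for co-dominant diploid data.
#
# .wc_locus computes, for one locus, the per-allele components
#   a: among populations, b: among individuals within populations,
#   c: within individuals (between gametes)
# from allele vectors x1, x2 (NA = missing call) and the population index g.
# With a single population only b and c are defined (a = 0 rows).
.wc_locus <- function(x1, x2, g) {
  obs <- !is.na(x1)
  x1 <- x1[obs]; x2 <- x2[obs]; g <- g[obs]
  pops <- sort(unique(g))
  r <- length(pops)
  ni <- as.numeric(tabulate(match(g, pops), nbins = r))
  if (any(ni == 0) || length(x1) == 0L) return(NULL)
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2L) return(NULL)        # monomorphic here: skip
  nbar <- mean(ni)
  if (r > 1 && nbar <= 1) return(NULL)
  gi <- match(g, pops)
  het <- x1 != x2
  k <- length(alleles)
  p <- matrix(0, r, k); h <- matrix(0, r, k)
  for (j in seq_len(k)) {
    a <- alleles[j]
    dose <- (x1 == a) + (x2 == a)
    p[, j] <- tapply(dose, gi, sum) / (2 * ni)
    h[, j] <- tapply(het & dose == 1L, gi, sum) / ni
  }
  if (r == 1L) {
    n <- ni[1]
    if (n <= 1) return(NULL)
    pbar <- p[1, ]; hbar <- h[1, ]
    b <- n / (n - 1) * (pbar * (1 - pbar) - (2 * n - 1) / (4 * n) * hbar)
    c_ <- hbar / 2
    return(cbind(a = rep(0, k), b = b, c = c_))
  }
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  cbind(a = a, b = b, c = c_)
}

# multilocus theta (ratio of summed components over loci and alleles)
.wc_theta <- function(ds, idx_list) {
  g <- rep(seq_along(idx_list), lengths(idx_list))
  idx <- unlist(idx_list)
  num <- 0; den <- 0
  for (l in seq_len(n_loci(ds))) {
    comp <- .wc_locus(ds$a1[idx, l], ds$a2[idx, l], g)
    if (is.null(comp)) next
    num <- num + sum(comp[, "a"])
    den <- den + sum(comp)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Weir-Cockerham F_ST with permutation significance
#'
#' Multilocus theta is the ratio of summed among-population variance
#' components to summed total components over loci and alleles (loci that
#' are monomorphic across the pair, or with undefined components, are
#' skipped).  Significance is assessed by permuting specimens between the
#' two populations; the P-value uses the add-one estimator
#' `(1 + #permuted >= observed) / (n_permutations + 1)`, so it is never 0.
#'
#' @param ds a [genotype_dataset()].
#' @param pop_a,pop_b population names (each with at least 2 specimens).
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `fst_result`: `pop_a`, `pop_b`, `theta`
#'   (reported as computed, negatives not clamped), `p_value`,
#'   `n_permutations`.  `theta` is `NA` with status `"undefined"` when no
#'   polymorphic locus informs the pair.
#' @export
pairwise_fst <- function(ds, pop_a, pop_b, n_permutations = 999, seed = 1L) {
  ia <- .pop_idx(ds, pop_a); ib <- .pop_idx(ds, pop_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both populations need at least 2 specimens")
  theta <- .wc_theta(ds, list(ia, ib))
  if (is.na(theta))
    return(structure(list(pop_a = pop_a, pop_b = pop_b, theta = NA_real_,
                          p_value = NA_real_, n_permutations = 0L,
                          status = "undefined"), class = "fst_result"))
  idx <- c(ia, ib); na <- length(ia)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(idx)
    th <- .wc_theta(ds, list(perm[seq_len(na)], perm[-seq_len(na)]))
    if (!is.na(th) && th >= theta) exceed <- exceed + 1L
  }
  structure(list(pop_a = pop_a, pop_b = pop_b, theta = theta,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 n_permutations = n_permutations, status = "ok"),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST(%s, %s) = %.2f  (P = %.4g, %d permutations)\n",
              x$pop_a, x$pop_b, x$theta, x$p_value, x$n_permutations))
  invisible(x)
}

#' All pairwise F_ST values among defined populations
#'
#' @inheritParams pairwise_fst
#' @param populations population names to compare (default: all defined).
#' @return a data.frame with one row per unordered pair: `pop_a`, `pop_b`,
#'   `theta`, `p_value`.
#' @export
fst_matrix <- function(ds, populations = NULL, n_permutations = 999,
                       seed = 1L) {
  if (is.null(populations)) populations <- population_partition(ds)$names
  pairs <- utils::combn(populations, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j)
    pairwise_fst(ds, pairs[1, j], pairs[2, j], n_permutations,
                 seed = seed + j))
  data.frame(pop_a = pairs[1, ], pop_b = pairs[2, ],
             theta = vapply(res, `[[`, numeric(1), "theta"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

# multilocus Weir-Cockerham f (F_IS) within one population
.wc_fis <- function(ds, idx) {
  g <- rep(1L, length(idx))
  sb <- 0; sc <- 0
  for (l in seq_len(n_loci(ds))) {
    comp <- .wc_locus(ds$a1[idx, l], ds$a2[idx, l], g)
    if (is.null(comp)) next
    sb <- sb + sum(comp[, "b"])
    sc <- sc + sum(comp[, "c"])
  }
  if (sb + sc == 0) return(NA_real_)
  1 - sc / (sb + sc)
}
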