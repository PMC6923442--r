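#' Per-population diversity summary
#'
#' Computes, for one population, the row of a classic SSR diversity table:
#' mean (and SD) number of alleles per locus (Na), private alleles (Pa,
#' alleles observed in this population and in no other defined
#' population), mean unbiased expected heterozygosity
#' (Nei's gene diversity with the `2n/(2n-1)` small-sample factor), mean
#' observed heterozygosity, the multilocus Weir-Cockerham fixation index
#' f (F_IS) with a permutation P-value (gene copies re-paired among
#' individuals within the population), and the E5 evenness of the
#' multilocus-genotype frequency spectrum.
#'
#' @param ds a [genotype_dataset()].
#' @param population population name.
#' @param n_permutations permutations for the F_IS test (default 999).
#' @param seed RNG seed for the permutation test.
#' @param exclude_monomorphic if `TRUE`, loci monomorphic *within this
#'   population* are excluded from the Na/Hexp/Hobs means (default
#'   `FALSE`: all loci contribute, a monomorphic locus adding
#'   Na = 1 and Hexp = Hobs = 0).
#' @return a list of class `population_summary` with fields `population`,
#'   `n_specimens`, `n_umlg`, `na_mean`, `na_sd`, `private_alleles`,
#'   `hexp_mean`, `hobs_mean`, `fis`, `fis_p`, `evenness_e5`.  `fis` is
#'   `NA` for a single-specimen population; `evenness_e5` is `NA` with
#'   fewer than two distinct MLGs.
#' @export
summarize_population <- function(ds, population, n_permutations = 999,
                                 seed = 1L, exclude_monomorphic = FALSE) {
  idx <- .pop_idx(ds, population)
  if (!length(idx)) stop("population is empty: ", population)
  part <- population_partition(ds)
  others <- setdiff(part$names, population)

  L <- n_loci(ds)
  na <- numeric(L); hexp <- numeric(L); hobs <- numeric(L)
  informative <- logical(L)
  pa <- 0L
  for (l in seq_len(L)) {
    x1 <- ds$a1[idx, l]; x2 <- ds$a2[idx, l]
    obs <- !is.na(x1)
    nl <- sum(obs)
    if (nl == 0L) { na[l] <- NA; hexp[l] <- NA; hobs[l] <- NA; next }
    alle <- c(x1[obs], x2[obs])
    tab <- table(alle)
    na[l] <- length(tab)
    informative[l] <- TRUE
    p <- as.numeric(tab) / sum(tab)
    hexp[l] <- (2 * nl / (2 * nl - 1)) * (1 - sum(p^2))
    hobs[l] <- mean(x1[obs] != x2[obs])
    # private alleles at this locus
    here <- as.integer(names(tab))
    if (length(others)) {
      elsewhere <- unique(unlist(lapply(others, function(q) {
        iq <- match(part$members[[q]], ds$specimen_ids)
        v <- c(ds$a1[iq, l], ds$a2[iq, l])
        v[!is.na(v)]
      })))
      pa <- pa + sum(!here %in% elsewhere)
    }
  }
  use <- informative & (!exclude_monomorphic | na > 1)

  # F_IS with permutation (re-pair gene copies within the population)
  fis <- if (length(idx) >= 2L) .wc_fis(ds, idx) else NA_real_
  fis_p <- NA_real_
  if (!is.na(fis) && n_permutations > 0) {
    set.seed(seed)
    exceed <- 0L
    dsp <- ds
    for (b in seq_len(n_permutations)) {
      for (l in seq_len(L)) {
        x1 <- ds$a1[idx, l]; x2 <- ds$a2[idx, l]
        obs <- which(!is.na(x1))
        if (length(obs) < 2L) next
        copies <- sample(c(x1[obs], x2[obs]))
        m <- length(obs)
        dsp$a1[idx[obs], l] <- pmin(copies[1:m], copies[(m + 1):(2 * m)])
        dsp$a2[idx[obs], l] <- pmax(copies[1:m], copies[(m + 1):(2 * m)])
      }
      fp <- .wc_fis(dsp, idx)
      if (!is.na(fp) && fp >= fis) exceed <- exceed + 1L
    }
    fis_p <- (1 + exceed) / (n_permutations + 1)
  }

  structure(list(
    population = population,
    n_specimens = length(idx),
    n_umlg = count_unique_mlg(ds, population),
    na_mean = mean(na[use]), na_sd = sd(na[use]),
    private_alleles = pa,
    hexp_mean = mean(hexp[use]), hobs_mean = mean(hobs[use]),
    fis = fis, fis_p = fis_p,
    evenness_e5 = mlg_evenness(ds, population)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "%s: n=%d uMLG=%d Na=%.2f+/-%.2f Pa=%d Hexp=%.2f Hobs=%.2f Fis=%.2f (P=%.3g) E5=%.2f\n",
    x$population, x$n_specimens, x$n_umlg, x$na_mean, x$na_sd,
    x$private_alleles, x$hexp_mean, x$hobs_mean, x$fis, x$fis_p,
    x$evenness_e5))
  invisible(x)
}

#' E5 evenness of the multilocus-genotype frequency spectrum
#'
#' `E5 = (1/lambda - 1) / (exp(H) - 1)` where `H` is the Shannon index and
#' `lambda` the Simpson concentration (`sum p_i^2`) of the MLG
#' frequencies; equivalently the ratio of Hill numbers `(N2-1)/(N1-1)`.
#' Equals 1 when all genotypes are equally frequent.
#'
#' @inheritParams count_unique_mlg
#' @return evenness in \[0, 1\], or `NA` with fewer than 2 distinct MLGs.
#' @export
mlg_evenness <- function(ds, population) {
  idx <- .pop_idx(ds, population)
  key <- vapply(idx, function(i)
    paste(ds$a1[i, ], ds$a2[i, ], collapse = "|"), character(1))
  p <- as.numeric(table(key)) / length(key)
  if (length(p) < 2L) return(NA_real_)
  H <- -sum(p * log(p))
  lambda <- sum(p^2)
  (1 / lambda - 1) / (exp(H) - 1)
}

#' Diversity summaries for every defined population
#'
#' @inheritParams summarize_population
#' @return a data.frame with one row per population (Table-2 style).
#' @export
summarize_populations <- function(ds, n_permutations = 999, seed = 1L,
                                  exclude_monomorphic = FALSE) {
  pops <- population_partition(ds)$names
  rows <- lapply(seq_along(pops), function(j) {
    s <- summarize_population(ds, pops[j], n_permutations, seed + j,
                              exclude_monomorphic)
    data.frame(population = s$population, n_specimens = s$n_specimens,
               n_umlg = s$n_umlg, na_mean = s$na_mean, na_sd = s$na_sd,
               private_alleles = s$private_alleles,
               hexp_mean = s$hexp_mean, hobs_mean = s$hobs_mean,
               fis = s$fis, fis_p = s$fis_p,
               evenness_e5 = s$evenness_e5, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
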