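#' Allele frequencies at one locus within one population
#'
#' @param ds a [genotype_dataset()].
#' @param population population name.
#' @param locus locus name.
#' @return list with `freq` (named frequencies over observed alleles,
#'   summing to 1), `counts` (integer allele counts) and `n_genes`
#'   (2 x number of observed diploid calls).
#' @export
allele_frequencies <- function(ds, population, locus) {
  li <- match(locus, ds$loci)
  if (is.na(li)) stop("unknown locus: ", locus)
  idx <- .pop_idx(ds, population)
  alleles <- c(ds$a1[idx, li], ds$a2[idx, li])
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles))
    stop("no observed calls at locus ", locus, " in population ", population,
         ": frequencies undefined")
  counts <- table(alleles)
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  list(freq = cnt / sum(cnt), counts = cnt, n_genes = sum(cnt))
}

#' Encode genotypes as an allele-dosage matrix
#'
#' One column per (locus, allele) pair observed anywhere in the dataset;
#' entries are allele counts 0/1/2 per specimen.  Missing calls are
#' mean-imputed per column (the adegenet convention), so column means are
#' preserved.
#'
#' @param ds a [genotype_dataset()].
#' @param impute mean-impute missing dosages (default `TRUE`); with
#'   `FALSE`, missing calls yield `NA` entries.
#' @return numeric matrix (specimens x alleles) with `locus.allele`
#'   column names.
#' @export
encode_alleles <- function(ds, impute = TRUE) {
  n <- n_specimens(ds)
  cols <- list()
  for (l in seq_len(n_loci(ds))) {
    x1 <- ds$a1[, l]; x2 <- ds$a2[, l]
    alleles <- sort(unique(c(x1, x2)[!is.na(c(x1, x2))]))
    for (a in alleles) {
      d <- (x1 == a) + (x2 == a)
      if (impute && anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
      cols[[paste0(ds$loci[l], ".", a)]] <- d
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ds$specimen_ids
  m
}
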