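#' Remove specimens with too much missing data
#'
#' Drops every specimen whose fraction of missing locus calls is strictly
#' greater than `max_missing_fraction` (use `strict = FALSE` for
#' greater-or-equal).  The removed ids are attached to the result as
#' attribute `"removed"`.
#'
#' @param ds a [genotype_dataset()].
#' @param max_missing_fraction missingness threshold in \[0, 1\]
#'   (default 0.10).
#' @param strict if `TRUE` (default) remove only specimens strictly above
#'   the threshold.
#' @return the filtered `genotype_dataset`, with attribute `removed`
#'   (character ids, input order).  An empty result raises a warning, not
#'   an error.
#' @export
filter_missing_specimens <- function(ds, max_missing_fraction = 0.10,
                                     strict = TRUE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  mf <- missing_fraction(ds)
  drop <- if (strict) mf > max_missing_fraction else mf >= max_missing_fraction
  if (all(drop)) warning("all specimens removed by missingness filter")
  out <- subset_dataset(ds, specimens = !drop)
  attr(out, "removed") <- ds$specimen_ids[drop]
  out
}

#' Remove monomorphic loci
#'
#' Drops loci with at most one distinct observed allele across all
#' non-missing calls (all-missing loci are also dropped).  Removed locus
#' names are attached as attribute `"removed"`.
#'
#' @param ds a [genotype_dataset()].
#' @return the filtered `genotype_dataset` with attribute `removed`.
#' @export
drop_monomorphic_loci <- function(ds) {
  nall <- vapply(seq_len(n_loci(ds)), function(l) {
    length(unique(c(ds$a1[, l], ds$a2[, l])[!is.na(c(ds$a1[, l], ds$a2[, l]))]))
  }, integer(1))
  drop <- nall <= 1L
  if (all(drop)) warning("all loci are monomorphic")
  out <- subset_dataset(ds, loci = !drop)
  attr(out, "removed") <- ds$loci[drop]
  out
}

#' Count unique multilocus genotypes (uMLG) in a population
#'
#' Two specimens carry the same multilocus genotype when every locus call
#' matches.  With missing data the default rule is conservative: specimens
#' match only if all mutually observed loci agree *and* their missing
#' patterns are identical.  With `missing_matches_any = TRUE` a missing
#' call is compatible with anything (genotypes are then merged by
#' transitive closure of pairwise compatibility).
#'
#' @param ds a [genotype_dataset()].
#' @param population population name.
#' @param missing_matches_any relaxed matching rule (default `FALSE`).
#' @return integer count in \[1, n\].
#' @export
count_unique_mlg <- function(ds, population, missing_matches_any = FALSE) {
  idx <- .pop_idx(ds, population)
  n <- length(idx)
  if (n == 0L) stop("population is empty: ", population)
  if (!missing_matches_any) {
    key <- vapply(idx, function(i)
      paste(ds$a1[i, ], ds$a2[i, ], collapse = "|"), character(1))
    return(length(unique(key)))
  }
  # union-find over pairwise-compatible specimens
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ii <- idx[i]; jj <- idx[j]
    obs <- !is.na(ds$a1[ii, ]) & !is.na(ds$a1[jj, ])
    ok <- all(ds$a1[ii, obs] == ds$a1[jj, obs] &
              ds$a2[ii, obs] == ds$a2[jj, obs])
    if (ok) parent[find(j)] <- find(i)
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' One-call quality control: missingness filter plus monomorphic-locus drop
#'
#' @param ds a [genotype_dataset()].
#' @param max_missing_fraction per-specimen missingness cut (default 0.10).
#' @param drop_monomorphic drop loci with a single observed allele.
#' @return list with `dataset` (the filtered data) and `report` (counts and
#'   removed ids/loci, suitable for JSON serialisation).
#' @export
qc_dataset <- function(ds, max_missing_fraction = 0.10,
                       drop_monomorphic = TRUE) {
  n0 <- n_specimens(ds); l0 <- n_loci(ds)
  ds1 <- filter_missing_specimens(ds, max_missing_fraction)
  removed_specimens <- attr(ds1, "removed")
  removed_loci <- character()
  if (drop_monomorphic) {
    ds1 <- drop_monomorphic_loci(ds1)
    removed_loci <- attr(ds1, "removed")
  }
  list(dataset = ds1,
       report = list(
         n_specimens_in = n0, n_specimens_retained = n_specimens(ds1),
         n_loci_in = l0, n_loci_retained = n_loci(ds1),
         max_missing_fraction = max_missing_fraction,
         removed_specimens = removed_specimens,
         removed_loci = removed_loci))
}
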