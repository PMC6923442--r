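#' Diploid multilocus microsatellite genotype dataset
#'
#' The central container of the package: diploid allele calls (integer
#' allele states, typically repeat numbers or fragment sizes) for a set of
#' specimens at a shared list of loci, together with per-specimen metadata
#' (population, infestation spot, host tree, life stage, mitochondrial
#' haplotype).
#'
#' Allele pairs are stored order-normalized (smaller allele first) in two
#' integer matrices `a1` and `a2` of dimension specimens x loci.  A call is
#' either fully observed (both alleles non-missing) or fully missing (both
#' `NA`); half-observed input calls are rejected.
#'
#' @param a1,a2 integer matrices (specimens x loci) with the two allele
#'   states per call; orientation is normalized internally.
#' @param specimen_ids character vector of unique specimen identifiers.
#' @param loci character vector of locus names.
#' @param metadata optional `data.frame` with one row per specimen;
#'   recognised columns are `population`, `spot`, `tree`, `stage`,
#'   `haplotype` (all optional).  Other columns are preserved.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, specimen_ids, loci, metadata = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(specimen_ids); L <- length(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be n_specimens x n_loci")
  if (anyDuplicated(specimen_ids))
    stop("duplicate specimen ids: ",
         paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls (one allele observed) are not allowed")
  # order-normalize: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (any(a1 < 0, na.rm = TRUE)) stop("allele states must be non-negative")
  dimnames(a1) <- dimnames(a2) <- list(specimen_ids, loci)
  if (is.null(metadata)) {
    metadata <- data.frame(id = specimen_ids, stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (nrow(metadata) != n) stop("metadata must have one row per specimen")
    metadata$id <- specimen_ids
  }
  for (col in c("population", "spot", "tree", "stage", "haplotype"))
    if (!col %in% names(metadata)) metadata[[col]] <- NA_character_
  rownames(metadata) <- NULL
  structure(
    list(specimen_ids = as.character(specimen_ids),
         loci = as.character(loci),
         a1 = a1, a2 = a2, metadata = metadata),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_specimens(x), "specimens x", n_loci(x), "loci\n")
  pops <- population_partition(x)
  if (length(pops$names))
    cat("populations:",
        paste(sprintf("%s (%d)", pops$names, lengths(pops$members)),
              collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of specimens / loci in a genotype dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_specimens <- function(ds) length(ds$specimen_ids)

#' @rdname n_specimens
#' @export
n_loci <- function(ds) length(ds$loci)

#' Population partition of a genotype dataset
#'
#' Populations are taken from the `population` metadata column; specimens
#' with no label are left out of the partition (the union of the partition
#' is a subset of the specimens).  Names are ordered by first appearance.
#'
#' @param ds a `genotype_dataset`.
#' @return list with `names` (ordered population names) and `members`
#'   (named list of specimen-id vectors).
#' @export
population_partition <- function(ds) {
  pop <- ds$metadata$population
  keep <- !is.na(pop)
  nm <- unique(pop[keep])
  members <- lapply(nm, function(p) ds$specimen_ids[keep & pop == p])
  names(members) <- nm
  list(names = nm, members = members)
}

#' Subset a genotype dataset by specimens or loci
#'
#' @param ds a `genotype_dataset`.
#' @param specimens character ids or logical/integer index; `NULL` keeps all.
#' @param loci locus names or index; `NULL` keeps all.
#' @return the subset `genotype_dataset`; input order is preserved.
#' @export
subset_dataset <- function(ds, specimens = NULL, loci = NULL) {
  si <- seq_along(ds$specimen_ids)
  if (!is.null(specimens)) {
    si <- if (is.character(specimens)) match(specimens, ds$specimen_ids)
          else si[specimens]
    if (anyNA(si)) stop("unknown specimen id")
  }
  li <- seq_along(ds$loci)
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, ds$loci) else li[loci]
    if (anyNA(li)) stop("unknown locus")
  }
  genotype_dataset(ds$a1[si, li, drop = FALSE], ds$a2[si, li, drop = FALSE],
                   ds$specimen_ids[si], ds$loci[li],
                   ds$metadata[si, setdiff(names(ds$metadata), "id"),
                               drop = FALSE])
}

#' Fraction of missing locus calls per specimen
#' @param ds a `genotype_dataset`.
#' @return named numeric vector in \[0, 1\].
#' @export
missing_fraction <- function(ds) {
  rowMeans(is.na(ds$a1))
}

#' Specimen ids belonging to one population
#' @param ds a `genotype_dataset`.
#' @param population population name (must exist in the partition).
#' @return character vector of specimen ids.
#' @export
population_members <- function(ds, population) {
  part <- population_partition(ds)
  if (!population %in% part$names)
    stop("unknown population: ", population)
  part$members[[population]]
}

# internal: row indices of a population
.pop_idx <- function(ds, population) {
  match(population_members(ds, population), ds$specimen_ids)
}
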