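#' Dialect configuration for delimited genotype tables
#'
#' Describes how a delimited metadata+genotype table maps onto the
#' genotype data model: the field separator, the missing-data token, the
#' metadata column names, and how locus columns are laid out (two columns
#' per locus, suffixed `_1`/`_2` by default).
#'
#' @param sep field separator (default `,`).
#' @param missing token marking a missing allele (default `NA`; the empty
#'   string is always treated as missing too).
#' @param id_col,population_col,spot_col,tree_col,stage_col,haplotype_col
#'   column names for specimen id and metadata; any of the metadata
#'   columns may be `NULL` (absent).
#' @param locus_suffixes the two suffixes distinguishing the allele
#'   columns of one locus.
#' @return a `table_dialect` list.
#' @export
table_dialect <- function(sep = ",", missing = "NA",
                          id_col = "id", population_col = "population",
                          spot_col = "spot", tree_col = "tree",
                          stage_col = "stage", haplotype_col = "haplotype",
                          locus_suffixes = c("_1", "_2")) {
  structure(list(sep = sep, missing = missing, id_col = id_col,
                 population_col = population_col, spot_col = spot_col,
                 tree_col = tree_col, stage_col = stage_col,
                 haplotype_col = haplotype_col,
                 locus_suffixes = locus_suffixes),
            class = "table_dialect")
}

#' Read a table dialect from a YAML file
#' @param path YAML file whose keys match the arguments of
#'   [table_dialect()].
#' @return a `table_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(table_dialect, cfg)
}

#' Read a delimited metadata + genotype table
#'
#' Expects one row per specimen with metadata columns and two allele
#' columns per locus (`<locus><suffix1>`, `<locus><suffix2>` per the
#' dialect).  A call with either allele missing is treated as fully
#' missing.
#'
#' @param path path to the delimited file (with header row).
#' @param dialect a [table_dialect()]; defaults to the comma dialect.
#' @return a [genotype_dataset()] with any mapped metadata attached.
#' @export
read_genotype_table <- function(path, dialect = table_dialect()) {
  d <- dialect
  df <- read.table(path, header = TRUE, sep = d$sep,
                   colClasses = "character", check.names = FALSE,
                   na.strings = character())
  if (is.null(d$id_col) || !d$id_col %in% names(df))
    stop("required id column '", d$id_col, "' not found in table")
  s1 <- d$locus_suffixes[1]; s2 <- d$locus_suffixes[2]
  meta_cols <- unlist(d[c("id_col", "population_col", "spot_col",
                          "tree_col", "stage_col", "haplotype_col")])
  c1 <- setdiff(names(df)[endsWith(names(df), s1)], meta_cols)
  loci <- substr(c1, 1, nchar(c1) - nchar(s1))
  c2 <- paste0(loci, s2)
  if (!length(loci)) stop("no locus columns matched suffixes ",
                          s1, "/", s2)
  if (!all(c2 %in% names(df)))
    stop("second-allele column missing for loci: ",
         paste(loci[!c2 %in% names(df)], collapse = ", "))
  tok2int <- function(x) {
    x <- trimws(x)
    x[x == d$missing | x == ""] <- NA
    bad <- !is.na(x) & !grepl("^[0-9]+$", x)
    if (any(bad))
      stop("non-integer allele token: '", x[bad][1], "'")
    as.integer(x)
  }
  a1 <- sapply(c1, function(cc) tok2int(df[[cc]]))
  a2 <- sapply(c2, function(cc) tok2int(df[[cc]]))
  if (nrow(df) == 1L) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  meta_col <- function(col) {
    if (is.null(col) || !col %in% names(df)) rep(NA_character_, nrow(df))
    else { v <- trimws(df[[col]]); v[v == d$missing | v == ""] <- NA; v }
  }
  md <- data.frame(population = meta_col(d$population_col),
                   spot = meta_col(d$spot_col),
                   tree = meta_col(d$tree_col),
                   stage = meta_col(d$stage_col),
                   haplotype = meta_col(d$haplotype_col),
                   stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, trimws(df[[d$id_col]]), loci, md)
}

#' Write a genotype dataset as a delimited metadata + genotype table
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param dialect a [table_dialect()] controlling separator, missing token
#'   and column naming.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path, dialect = table_dialect()) {
  d <- dialect
  enc <- function(m) {
    m <- apply(m, 2, as.character)
    m[is.na(m)] <- d$missing
    m
  }
  m1 <- enc(ds$a1); m2 <- enc(ds$a2)
  geno <- matrix("", n_specimens(ds), 2L * n_loci(ds))
  geno[, seq(1, ncol(geno), 2)] <- m1
  geno[, seq(2, ncol(geno), 2)] <- m2
  gnames <- character(ncol(geno))
  gnames[seq(1, ncol(geno), 2)] <- paste0(ds$loci, d$locus_suffixes[1])
  gnames[seq(2, ncol(geno), 2)] <- paste0(ds$loci, d$locus_suffixes[2])
  colnames(geno) <- gnames
  mdmap <- c(population = "population_col", spot = "spot_col",
             tree = "tree_col", stage = "stage_col",
             haplotype = "haplotype_col")
  md <- list()
  md[[d$id_col]] <- ds$specimen_ids
  for (field in names(mdmap)) {
    col <- d[[mdmap[[field]]]]
    if (!is.null(col)) {
      v <- ds$metadata[[field]]
      v[is.na(v)] <- d$missing
      md[[col]] <- v
    }
  }
  out <- cbind(as.data.frame(md, check.names = FALSE), geno)
  write.table(out, path, sep = d$sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
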