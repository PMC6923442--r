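#' Read a GenePop genotype file
#'
#' Parses the classic GenePop layout: a title line, one locus name per line
#' (or a single comma-separated line), then `POP` blocks of
#' `id , a1a2 a1a2 ...` records with 2- or 3-digit allele coding.
#' `0`, `00`, `0000` etc. denote a missing call.  Populations are labelled
#' `pop_1`, `pop_2`, ... in file order.
#'
#' @param path path to a GenePop file.
#' @return a [genotype_dataset()] with populations taken from POP blocks.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("GenePop parse error: no POP line after header (line ",
         ifelse(is.na(first_pop), "none", first_pop), ")")
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GenePop parse error: no locus names (line 2)")

  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  pop_no <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (toupper(trimws(ln)) == "POP") { pop_no <- pop_no + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("GenePop parse error: missing ',' separator (line ", i, ")")
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(calls) != length(loci))
      stop("GenePop parse error: ", length(calls), " calls for ",
           length(loci), " loci (line ", i, ")")
    if (id %in% ids)
      stop("GenePop parse error: duplicate specimen id '", id,
           "' (line ", i, ")")
    w <- nchar(calls)
    if (any(w %% 2L != 0L))
      stop("GenePop parse error: odd-width allele code (line ", i, ")")
    half <- w %/% 2L
    x1 <- as.integer(substr(calls, 1L, half))
    x2 <- as.integer(substr(calls, half + 1L, w))
    if (anyNA(x1) || anyNA(x2))
      stop("GenePop parse error: non-numeric allele code (line ", i, ")")
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    # a single missing haploid code marks the whole call missing
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop_", pop_no))
    rows1[[length(rows1) + 1L]] <- x1; rows2[[length(rows2) + 1L]] <- x2
  }
  if (!length(ids)) stop("GenePop parse error: no specimen records")
  genotype_dataset(do.call(rbind, rows1), do.call(rbind, rows2),
                   ids, loci,
                   data.frame(population = pops, stringsAsFactors = FALSE))
}

#' Write a genotype dataset to GenePop format
#'
#' Specimens are grouped into POP blocks by population label (unlabelled
#' specimens form a final block).  Allele states are zero-padded to a fixed
#' width (3 digits by default, widened if needed); missing calls are coded
#' as all zeros.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param digits allele code width (2 or 3); widened if alleles overflow.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "outbreakgen export", digits = 3L) {
  amax <- suppressWarnings(max(ds$a2, na.rm = TRUE))
  if (is.finite(amax)) digits <- max(digits, nchar(as.character(amax)))
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = digits, flag = "0")
  }
  pop <- ds$metadata$population
  pop[is.na(pop)] <- "_unassigned"
  out <- c(title, ds$loci)
  for (p in unique(pop)) {
    out <- c(out, "POP")
    for (i in which(pop == p)) {
      calls <- paste0(fmt(ds$a1[i, ]), fmt(ds$a2[i, ]))
      out <- c(out, paste(ds$specimen_ids[i], ",", paste(calls, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a genotype dataset in STRUCTURE two-row-per-individual format
#'
#' Each specimen occupies two rows: `id  pop_index  allele_at_locus_1 ...`.
#' Missing alleles are coded `-9`.  A header row with locus names is
#' written when `header = TRUE`.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param header write a locus-name header row.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ds, path, header = TRUE) {
  pop <- ds$metadata$population
  popidx <- match(pop, unique(pop[!is.na(pop)]))
  popidx[is.na(popidx)] <- 0L
  con <- file(path, "w"); on.exit(close(con))
  if (header) writeLines(paste(ds$loci, collapse = "\t"), con)
  enc <- function(m, i) {
    x <- m[i, ]; x[is.na(x)] <- -9L
    paste(c(ds$specimen_ids[i], popidx[i], x), collapse = "\t")
  }
  for (i in seq_len(n_specimens(ds))) {
    writeLines(enc(ds$a1, i), con)
    writeLines(enc(ds$a2, i), con)
  }
  invisible(path)
}
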