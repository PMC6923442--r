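# Builders for small in-code fixtures and independent oracles.

# quick dataset from a genotype string matrix: entries "a/b" or NA
ds_from_strings <- function(m, populations = NULL, loci = NULL, ...) {
  m <- as.matrix(m)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(m)))
  a1 <- matrix(NA_integer_, nrow(m), ncol(m))
  a2 <- a1
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!is.na(m[i, j])) {
      p <- as.integer(strsplit(m[i, j], "/")[[1]])
      a1[i, j] <- p[1]; a2[i, j] <- p[2]
    }
  }
  md <- data.frame(population = populations %||%
                     rep(NA_character_, nrow(m)))
  extra <- list(...)
  for (nm in names(extra)) md[[nm]] <- extra[[nm]]
  genotype_dataset(a1, a2, paste0("s", seq_len(nrow(m))),
                   loci, md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random dataset: r populations drifted from shared ancestral frequencies
random_dataset <- function(n_pops = 2, n_per_pop = 10, n_loci = 4,
                           n_alleles = 3, fst = 0.2, seed = 1) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  a1 <- matrix(NA_integer_, n, n_loci); a2 <- a1
  for (l in seq_len(n_loci)) {
    anc <- as.numeric(rdirichlet_one(rep(1, n_alleles)))
    for (p in seq_len(n_pops)) {
      pf <- if (fst > 0)
        as.numeric(rdirichlet_one(anc * (1 - fst) / fst))
      else anc
      rows <- (p - 1) * n_per_pop + seq_len(n_per_pop)
      draws <- matrix(sample(n_alleles, 2 * n_per_pop, TRUE, prob = pf),
                      ncol = 2)
      a1[rows, l] <- draws[, 1] * 2L + 8L    # repeat-number-like states
      a2[rows, l] <- draws[, 2] * 2L + 8L
    }
  }
  genotype_dataset(a1, a2, sprintf("s%03d", 1:n),
                   paste0("L", seq_len(n_loci)),
                   data.frame(population = rep(paste0("pop", seq_len(n_pops)),
                                               each = n_per_pop)))
}

rdirichlet_one <- function(alpha) {
  x <- rgamma(length(alpha), alpha)
  x / sum(x)
}

# standard parameter set for the default three-deme scenarios
sc5_params <- function(...) {
  modifyList(list(N_Ma1 = 500, N_Ma2 = 300, N_Br = 400, N_SRC = 2000,
                  Nb_Ma1 = 30, Nb_Ma2 = 15, Nb_Br = 30,
                  db_Ma1 = 2, db_Ma2 = 2, db_Br = 2,
                  t1 = 9, t2 = 7, t3 = 6,
                  mu_mean = 5e-4, gsm_p = 0.2), list(...))
}

one_deme_scenario <- function() {
  parse_scenario("scenario ONE\ndeme SRC size N ancestral")
}

# shared ABC fixture for the acceptance suite: SC5 vs SC6 reference
# table at 1e4 simulations per scenario (built once, reused)
acceptance_abc <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$tab)) {
      cache$priors <- default_priors(step2 = TRUE)
      cache$sample_config <- c(Ma1 = 34, Ma2 = 14, Br = 53)
      cache$scenarios <- default_scenarios()[c("SC6", "SC5")]
      cache$tab <- build_reference_table(
        cache$scenarios, cache$priors, 10000, cache$sample_config,
        n_loci = 13, seed = 17)
    }
    as.list(cache)
  }
})

# restrict a reference table to one scenario
table_subset <- function(tab, scenario) {
  keep <- tab$scenario == scenario
  out <- tab
  out$scenario <- droplevels(tab$scenario[keep])
  out$params <- tab$params[keep, , drop = FALSE]
  out$stats <- tab$stats[keep, , drop = FALSE]
  out
}

# ---- independent Weir-Cockerham oracle -------------------------------
# Direct ANOVA sums of squares on allele indicators, per allele and locus;
# deliberately a different derivation from the package's closed-form
# components.
oracle_wc_theta <- function(ds, pops) {
  part <- population_partition(ds)
  idx <- lapply(pops, function(p) match(part$members[[p]], ds$specimen_ids))
  num <- 0; den <- 0
  for (l in seq_len(n_loci(ds))) {
    x1 <- lapply(idx, function(i) ds$a1[i, l])
    x2 <- lapply(idx, function(i) ds$a2[i, l])
    keep <- lapply(x1, function(v) !is.na(v))
    x1 <- mapply(function(v, k) v[k], x1, keep, SIMPLIFY = FALSE)
    x2 <- mapply(function(v, k) v[k], x2, keep, SIMPLIFY = FALSE)
    ni <- lengths(x1)
    if (any(ni == 0)) next
    alleles <- sort(unique(unlist(c(x1, x2))))
    if (length(alleles) < 2) next
    r <- length(ni); ntot <- sum(ni)
    nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
    for (a in alleles) {
      # y[i][j, k] indicator
      ybar_ij <- mapply(function(v1, v2) ((v1 == a) + (v2 == a)) / 2,
                        x1, x2, SIMPLIFY = FALSE)
      ybar_i <- vapply(ybar_ij, mean, numeric(1))
      ybar <- sum(ni * ybar_i) / ntot
      SSG <- sum(unlist(mapply(function(v1, v2, yb)
        ((v1 == a) - yb)^2 + ((v2 == a) - yb)^2,
        x1, x2, ybar_ij, SIMPLIFY = FALSE)))
      SSI <- 2 * sum(unlist(mapply(function(yb, yi) (yb - yi)^2,
                                   ybar_ij, ybar_i, SIMPLIFY = FALSE)))
      SSP <- 2 * sum(ni * (ybar_i - ybar)^2)
      MSG <- SSG / ntot
      MSI <- SSI / (ntot - r)
      MSP <- SSP / (r - 1)
      s2a <- (MSP - MSI) / (2 * nc)
      s2b <- (MSI - MSG) / 2
      s2c <- MSG
      num <- num + s2a
      den <- den + s2a + s2b + s2c
    }
  }
  num / den
}
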