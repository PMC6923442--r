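# "Paper-like" preset: a deterministic synthetic four-outbreak survey.
#
# The preset reconstructs, by design rather than by chance, the summary
# structure of a fine-scale SSR survey of four invasive outbreaks plus
# unassigned single findings: 223 specimens of which 31 exceed the 10%
# missingness cut (192 retained), 15 loci of which 2 are globally
# monomorphic; per-population allele richness, private-allele counts and
# heterozygote deficit planted via quota-rounded genotype counts; and a
# three-deme substructure (Marly #1, Marly #2, Bruenisried) whose
# pairwise Weir-Cockerham theta values are calibrated at the frequency
# level to 0.12 / 0.08 / 0.14, with the remaining population pairs
# strongly differentiated.  Retained specimens are fully observed, so
# every planted quantity is reproducible exactly; only the 31 discarded
# specimens and cosmetic orderings consume random numbers.

# ---- static design tables -------------------------------------------

.paperlike_design <- function() {
  fr <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  loci <- list(
    # loci 1-3: monomorphic within every population, fixed differences
    list(B = fr(`10` = 1), W = fr(`12` = 1), M = fr(`14` = 1),
         R = fr(`14` = 1), S = fr(`10` = .5, `12` = .25, `14` = .25)),
    list(B = fr(`12` = 1), W = fr(`14` = 1), M = fr(`10` = 1),
         R = fr(`10` = 1), S = fr(`10` = .5, `12` = .25, `14` = .25)),
    list(B = fr(`14` = 1), W = fr(`10` = 1), M = fr(`12` = 1),
         R = fr(`12` = 1), S = fr(`10` = .5, `12` = .25, `14` = .25)),
    # locus 4: private alleles 14 (Marly) and 22 (Bruenisried)
    list(B = fr(`10` = 1), W = fr(`12` = 1),
         M = fr(`10` = .55, `12` = .35, `14` = .10),
         R = fr(`10` = .60, `12` = .32, `22` = .08),
         S = fr(`10` = .5, `12` = .5)),
    # locus 5: private 18 (Berikon), 24 (Marly)
    list(B = fr(`10` = .55, `12` = .30, `18` = .15),
         W = fr(`12` = .75, `16` = .25),
         M = fr(`10` = .55, `12` = .35, `24` = .10),
         R = fr(`10` = .50, `12` = .30, `16` = .20),
         S = fr(`10` = .5, `12` = .5)),
    # locus 6: private 24 (Marly)
    list(B = fr(`10` = .50, `12` = .30, `14` = .20),
         W = fr(`10` = .75, `14` = .25),
         M = fr(`10` = .50, `12` = .40, `24` = .10),
         R = fr(`10` = .45, `12` = .35, `14` = .20),
         S = fr(`10` = .5, `12` = .5)),
    # locus 7: private 24 (Marly)
    list(B = fr(`10` = .60, `12` = .25, `14` = .15),
         W = fr(`12` = .80, `14` = .20),
         M = fr(`10` = .55, `12` = .35, `24` = .10),
         R = fr(`10` = .50, `12` = .30, `14` = .20),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .70, `12` = .30),
         W = fr(`10` = .75, `12` = .25),
         M = fr(`10` = .45, `12` = .35, `14` = .20),
         R = fr(`10` = .50, `12` = .30, `14` = .20),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .55, `12` = .30, `14` = .15),
         W = fr(`10` = .80, `12` = .20),
         M = fr(`10` = .50, `12` = .30, `14` = .20),
         R = fr(`10` = .50, `12` = .35, `14` = .15),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .50, `12` = .35, `14` = .15),
         W = fr(`10` = .75, `14` = .25),
         M = fr(`10` = .55, `12` = .30, `14` = .15),
         R = fr(`10` = .65, `12` = .35),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .70, `12` = .30),
         W = fr(`10` = .80, `16` = .20),
         M = fr(`10` = .50, `12` = .35, `16` = .15),
         R = fr(`10` = .60, `12` = .40),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .75, `12` = .25),
         W = fr(`10` = .70, `12` = .20, `14` = .10),
         M = fr(`10` = .50, `12` = .30, `14` = .20),
         R = fr(`10` = .70, `12` = .30),
         S = fr(`10` = .5, `12` = .5)),
    list(B = fr(`10` = .70, `12` = .30),
         W = fr(`10` = .70, `12` = .20, `16` = .10),
         M = fr(`10` = .45, `12` = .30, `14` = .15, `16` = .10),
         R = fr(`10` = .55, `12` = .30, `14` = .15),
         S = fr(`10` = .5, `12` = .5)))
  list(
    loci = loci,
    n_mono_loci = 2L, mono_allele = 20L,
    sizes = c(Berikon = 20L, Bruenisried = 53L, Marly1 = 34L,
              Marly2 = 14L, MarlyX = 14L, Winterthur = 49L,
              Single = 8L),
    extras = c(Berikon = 4L, Bruenisried = 8L, Marly = 10L,
               Winterthur = 8L, Single = 1L),
    fis = c(Berikon = 0.32, Bruenisried = 0.29, Marly1 = 0.20,
            Marly2 = 0.20, MarlyX = 0.20, Winterthur = 0.01,
            Single = 0.0),
    # pairwise theta targets among the Marly/Bruenisried demes
    theta_targets = c(ma1_ma2 = 0.12, ma1_br = 0.08, ma2_br = 0.14),
    trees = c(Berikon = 1L, Bruenisried = 11L, Marly = 35L,
              Winterthur = 20L),
    haplotype = c(Berikon = "A", Bruenisried = "C", Marly = "C",
                  Winterthur = "A", Single = "A/B"))
}

# ---- frequency-level theta (expected-count Weir-Cockerham) -----------

# theta between two demes from frequency profiles, sample sizes and the
# within-deme inbreeding used for the heterozygosity correction terms
.wc_theta_freq <- function(pa_list, pb_list, na, nb, fa = 0, fb = 0) {
  num <- 0; den <- 0
  for (l in seq_along(pa_list)) {
    alleles <- union(names(pa_list[[l]]), names(pb_list[[l]]))
    if (length(alleles) < 2) next
    pa <- pa_list[[l]][alleles]; pa[is.na(pa)] <- 0
    pb <- pb_list[[l]][alleles]; pb[is.na(pb)] <- 0
    ni <- c(na, nb); r <- 2
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    p <- rbind(pa, pb)
    h <- rbind(2 * pa * (1 - pa) * (1 - fa), 2 * pb * (1 - pb) * (1 - fb))
    pbar <- colSums(ni * p) / (r * nbar)
    s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(ni * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - s2 / r - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / r - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + sum(a); den <- den + sum(a + b + cc)
  }
  num / den
}

# transfer mass `amt` from allele j to allele i (by name), floor 0.02
.freq_shift <- function(p, i, j, amt) {
  amt <- min(amt, p[j] - 0.02)
  if (amt < 0) amt <- 0
  p[i] <- p[i] + amt
  p[j] <- p[j] - amt
  p
}

# deme frequency profiles for Marly #1, Marly #2 and Bruenisried given
# calibration scales (c1, c2, c0)
.paperlike_deme_freqs <- function(design, cc) {
  c1 <- cc[1]; c2 <- cc[2]; c0 <- cc[3]
  loci <- design$loci
  ma1 <- list(); ma2 <- list(); br <- list()
  for (l in seq_along(loci)) {
    pm <- loci[[l]]$M
    pr <- loci[[l]]$R
    if (length(pm) >= 2) {
      ma1[[l]] <- .freq_shift(pm, 1, 2, c1 * 0.5)
      k <- length(pm)
      ma2[[l]] <- .freq_shift(pm, k, 1, c2 * 0.5)
    } else {
      ma1[[l]] <- pm; ma2[[l]] <- pm
    }
    # push Bruenisried's shared-allele profile away from the Marly base
    if (length(pr) >= 2) {
      shared <- intersect(names(pr), names(pm))
      if (length(shared) >= 2) {
        d <- pr[shared] / sum(pr[shared]) - pm[shared] / sum(pm[shared])
        pnew <- pr
        pnew[shared] <- pmax(pr[shared] + c0 * d * sum(pr[shared]), 0.02)
        pnew[shared] <- pnew[shared] / sum(pnew[shared]) * sum(pr[shared])
        br[[l]] <- pnew
      } else br[[l]] <- pr
    } else br[[l]] <- pr
  }
  list(ma1 = ma1, ma2 = ma2, br = br)
}

.paperlike_calibrate <- function(design) {
  tg <- design$theta_targets
  nn <- design$sizes
  f <- design$fis
  clip <- function(cc) pmin(pmax(cc, 0), c(2, 2, 8))
  obj_freq <- function(cc) {
    cc <- clip(cc)
    fq <- .paperlike_deme_freqs(design, cc)
    t12 <- .wc_theta_freq(fq$ma1, fq$ma2, nn["Marly1"], nn["Marly2"],
                          f["Marly1"], f["Marly2"])
    t1b <- .wc_theta_freq(fq$ma1, fq$br, nn["Marly1"], nn["Bruenisried"],
                          f["Marly1"], f["Bruenisried"])
    t2b <- .wc_theta_freq(fq$ma2, fq$br, nn["Marly2"], nn["Bruenisried"],
                          f["Marly2"], f["Bruenisried"])
    (t12 - tg["ma1_ma2"])^2 + (t1b - tg["ma1_br"])^2 + (t2b - tg["ma2_br"])^2
  }
  fit <- stats::optim(c(0.3, 0.6, 1.0), obj_freq, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  # refine against the quota-realized blocks (deterministic), absorbing
  # integer-rounding and heterozygosity-correction effects
  obj_real <- function(cc) {
    cc <- clip(cc)
    fq <- .paperlike_deme_freqs(design, cc)
    b1 <- .deme_block(fq$ma1, nn[["Marly1"]], f[["Marly1"]], refine_f = FALSE)
    b2 <- .deme_block(fq$ma2, nn[["Marly2"]], f[["Marly2"]], refine_f = FALSE)
    bb <- .deme_block(fq$br, nn[["Bruenisried"]], f[["Bruenisried"]],
                      refine_f = FALSE)
    (.blocks_theta(b1, b2) - tg["ma1_ma2"])^2 +
      (.blocks_theta(b1, bb) - tg["ma1_br"])^2 +
      (.blocks_theta(b2, bb) - tg["ma2_br"])^2
  }
  fit2 <- stats::optim(clip(fit$par), obj_real, method = "Nelder-Mead",
                       control = list(maxit = 80, reltol = 1e-6))
  clip(fit2$par)
}

# multilocus theta between two deme blocks
.blocks_theta <- function(ba, bb) {
  na <- nrow(ba$a1); nb <- nrow(bb$a1)
  g <- rep(1:2, c(na, nb))
  num <- 0; den <- 0
  for (l in seq_len(ncol(ba$a1))) {
    comp <- .wc_locus(c(ba$a1[, l], bb$a1[, l]),
                      c(ba$a2[, l], bb$a2[, l]), g)
    if (is.null(comp)) next
    num <- num + sum(comp[, "a"]); den <- den + sum(comp)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# ---- genotype quota construction -------------------------------------

# allocate `H` heterozygotes among allele pairs proportional to p_a*p_b,
# respecting per-allele copy caps and even homozygote leftovers; returns
# the pair-count matrix (upper triangle).  The realized total may differ
# from H by the parity repair.
.alloc_hets <- function(counts, H) {
  k <- length(counts)
  p <- counts / sum(counts)
  w <- outer(p, p)
  w[lower.tri(w, diag = TRUE)] <- 0
  h <- matrix(0L, k, k)
  if (sum(w) > 0 && H > 0) {
    tri <- which(w > 0)
    h[tri] <- .quota_round(w[tri], as.integer(H))
  }
  used <- function() rowSums(h) + colSums(h)
  repeat {
    over <- which(used() > counts)
    if (!length(over)) break
    a <- over[1]
    cand <- which(h[a, ] > 0 | h[, a] > 0)
    j <- cand[which.max(pmax(h[a, cand], h[cand, a]))]
    if (h[a, j] > 0) h[a, j] <- h[a, j] - 1L else h[j, a] <- h[j, a] - 1L
  }
  leftover <- counts - used()
  odd <- which(leftover %% 2 == 1)
  while (length(odd) >= 2) {
    a <- odd[1]; b <- odd[2]
    i <- min(a, b); j <- max(a, b)
    tot <- sum(h)
    # move toward H: drop a het if above target and possible, else add
    if (tot > H && h[i, j] > 0) h[i, j] <- h[i, j] - 1L
    else h[i, j] <- h[i, j] + 1L
    leftover <- counts - used()
    odd <- which(leftover %% 2 == 1)
  }
  h
}

# genotype rows from a pair-count matrix
.geno_rows <- function(allele_states, counts, h) {
  k <- length(allele_states)
  leftover <- counts - (rowSums(h) + colSums(h))
  rows <- list()
  for (i in seq_len(k)) {
    if (leftover[i] > 0)
      rows[[length(rows) + 1]] <-
        matrix(rep(allele_states[i], leftover[i]), ncol = 2)
    for (j in seq_len(k))
      if (h[i, j] > 0)
        rows[[length(rows) + 1]] <-
          matrix(rep(c(allele_states[i], allele_states[j]), h[i, j]),
                 ncol = 2, byrow = TRUE)
  }
  do.call(rbind, rows)
}

# multilocus Weir-Cockerham f from a list of per-locus genotype matrices
.blocks_fis <- function(geno) {
  sb <- 0; sc <- 0
  for (g in geno) {
    comp <- .wc_locus(g[, 1], g[, 2], rep(1L, nrow(g)))
    if (is.null(comp)) next
    sb <- sb + sum(comp[, "b"]); sc <- sc + sum(comp[, "c"])
  }
  if (sb + sc == 0) return(NA_real_)
  1 - sc / (sb + sc)
}

# full genotype block for one deme: quota-rounded allele counts, then a
# greedy search over per-locus heterozygote totals so the realized
# multilocus f lands on the target despite integer/parity granularity
.deme_block <- function(freq_list, n, f, refine_f = TRUE) {
  L <- length(freq_list)
  states <- lapply(freq_list, function(p) as.integer(names(p)))
  counts <- lapply(freq_list, function(p)
    .quota_round(p, 2L * n, min_count = 1L))
  H <- vapply(seq_len(L), function(l) {
    p <- counts[[l]] / sum(counts[[l]])
    as.integer(round(n * (1 - sum(p^2)) * (1 - f)))
  }, integer(1))
  build <- function(H) lapply(seq_len(L), function(l) {
    if (length(states[[l]]) == 1L)
      matrix(rep(states[[l]], 2L * n), n, 2)
    else .geno_rows(states[[l]], counts[[l]],
                    .alloc_hets(counts[[l]], H[l]))
  })
  geno <- build(H)
  err <- abs(.blocks_fis(geno) - f)
  if (!refine_f) err <- -Inf     # skip the greedy refinement below
  for (iter in seq_len(3 * L)) {
    if (is.infinite(err)) break
    best <- NULL
    for (l in seq_len(L)) {
      if (length(states[[l]]) == 1L) next
      for (dlt in c(-1L, 1L)) {
        Ht <- H; Ht[l] <- max(0L, Ht[l] + dlt)
        gt <- build(Ht)
        e <- abs(.blocks_fis(gt) - f)
        if (!is.na(e) && e < err - 1e-9) { err <- e; best <- list(Ht, gt) }
      }
    }
    if (is.null(best)) break
    H <- best[[1]]; geno <- best[[2]]
  }
  a1 <- vapply(geno, function(g) pmin(g[, 1], g[, 2]), integer(n))
  a2 <- vapply(geno, function(g) pmax(g[, 1], g[, 2]), integer(n))
  list(a1 = matrix(a1, n), a2 = matrix(a2, n))
}

#' Deterministic "paper-like" synthetic four-outbreak dataset
#'
#' Builds a synthetic SSR survey with the structure of a fine-scale
#' invasion study: four outbreak populations (Berikon, Bruenisried,
#' Marly, Winterthur) plus unassigned single findings; 223 specimens of
#' which 31 carry >10% missing calls; 15 loci of which 2 are globally
#' monomorphic.  Within Marly, two infestation spots (`Marly #1`,
#' `Marly #2`; 14 further specimens carry no spot label) and the
#' Bruenisried deme are calibrated to pairwise Weir-Cockerham theta of
#' about 0.12 (Ma1-Ma2), 0.08 (Ma1-Br) and 0.14 (Ma2-Br), the remaining
#' pairs being strongly differentiated; per-population allele richness,
#' private alleles and heterozygote deficit are planted by quota-rounded
#' genotype counts, so they do not vary with the seed.  Retained
#' specimens are fully observed; the random seed affects only the
#' genotypes and missing patterns of the 31 high-missingness specimens.
#'
#' @param seed RNG seed (high-missingness specimens, orderings).
#' @return list with `dataset` (a [genotype_dataset()], 223 specimens x
#'   15 loci) and `truth` (design targets: planted F_IS and theta
#'   targets, expected QC counts, deme composition).
#' @export
make_paperlike_dataset <- function(seed = 1L) {
  set.seed(seed)
  design <- .paperlike_design()
  cc <- .paperlike_calibrate(design)
  fq <- .paperlike_deme_freqs(design, cc)
  loci13 <- design$loci
  nn <- design$sizes; f <- design$fis

  profiles <- list(
    Berikon = lapply(loci13, `[[`, "B"),
    Bruenisried = fq$br,
    Marly1 = fq$ma1,
    Marly2 = fq$ma2,
    MarlyX = lapply(loci13, `[[`, "M"),
    Winterthur = lapply(loci13, `[[`, "W"),
    Single = lapply(loci13, `[[`, "S"))

  blocks <- lapply(names(profiles), function(g)
    .deme_block(profiles[[g]], nn[[g]], f[[g]]))
  names(blocks) <- names(profiles)

  a1 <- do.call(rbind, lapply(blocks, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(blocks, `[[`, "a2"))
  deme <- rep(names(profiles), nn)
  pop <- c(Berikon = "Berikon", Bruenisried = "Bruenisried",
           Marly1 = "Marly", Marly2 = "Marly", MarlyX = "Marly",
           Winterthur = "Winterthur", Single = "Single findings")[deme]
  spot <- rep(NA_character_, length(deme))
  spot[deme == "Marly1"] <- "Marly #1"
  spot[deme == "Marly2"] <- "Marly #2"

  # 31 extra specimens with >10% missing loci, removed by the QC cut
  ex <- design$extras
  ex_pop <- rep(names(ex), ex)
  ex_pop[ex_pop == "Single"] <- "Single findings"
  ex_profile <- c(Berikon = "Berikon", Bruenisried = "Bruenisried",
                  Marly = "MarlyX", Winterthur = "Winterthur",
                  `Single findings` = "Single")[ex_pop]
  n_ex <- length(ex_pop)
  e1 <- matrix(NA_integer_, n_ex, 13); e2 <- e1
  for (i in seq_len(n_ex)) {
    prof <- profiles[[ex_profile[i]]]
    for (l in seq_len(13)) {
      p <- prof[[l]]
      states <- as.integer(names(p))
      draw <- if (length(states) == 1L) rep(states, 2)
              else sample(states, 2, TRUE, prob = p)
      e1[i, l] <- min(draw); e2[i, l] <- max(draw)
    }
  }
  a1 <- rbind(a1, e1); a2 <- rbind(a2, e2)
  pop <- c(pop, ex_pop)
  spot <- c(spot, rep(NA_character_, n_ex))

  # append the two globally monomorphic loci
  n_tot <- nrow(a1)
  mono <- matrix(design$mono_allele, n_tot, design$n_mono_loci)
  a1 <- cbind(a1, mono); a2 <- cbind(a2, mono)

  # mask 3-6 of the 15 loci in each extra specimen (>10% missing)
  for (i in seq_len(n_ex)) {
    k <- sample(3:6, 1)
    drop <- sample(15, k)
    a1[nrow(a1) - n_ex + i, drop] <- NA_integer_
    a2[nrow(a2) - n_ex + i, drop] <- NA_integer_
  }

  # metadata: trees round-robin within outbreaks, haplotypes by origin
  tree <- rep(NA_character_, n_tot)
  for (p in names(design$trees)) {
    rows <- which(pop == p)
    tr <- rep(seq_len(design$trees[[p]]), length.out = length(rows))
    tree[rows] <- sprintf("%s_tree%02d", p, tr)
  }
  hap <- rep(NA_character_, n_tot)
  for (p in names(design$haplotype)) {
    rows <- which(startsWith(pop, substr(p, 1, 6)))
    hap[rows] <- design$haplotype[[p]]
  }
  hap[pop == "Single findings"] <-
    rep(c("A", "B"), length.out = sum(pop == "Single findings"))

  ids <- sprintf("ALB%03d", seq_len(n_tot))
  ds <- genotype_dataset(a1, a2, ids,
                         sprintf("SSR%02d", seq_len(15L)),
                         data.frame(population = pop, spot = spot,
                                    tree = tree, stage = NA_character_,
                                    haplotype = hap,
                                    stringsAsFactors = FALSE))
  list(dataset = ds,
       truth = list(
         calibration = cc,
         theta_targets = design$theta_targets,
         fis_targets = design$fis,
         expected_retained = sum(design$sizes),
         expected_removed = sum(design$extras),
         expected_polymorphic_loci = 13L,
         deme = c(deme, ex_profile)))
}

#' Relabel the Marly spots and Bruenisried as analysis demes
#'
#' Subsets a dataset to the specimens of the two interconnected
#' outbreaks and relabels `population` as the three demes used in the
#' demographic reconstruction: `Ma1` (Marly #1), `Ma2` (Marly #2) and
#' `Br` (Bruenisried).  Marly specimens without a spot label are dropped,
#' as are all other populations.
#'
#' @param ds a [genotype_dataset()] with `spot` metadata.
#' @param marly,bruenisried population labels in `ds`.
#' @return a [genotype_dataset()] with populations Ma1/Ma2/Br.
#' @export
marly_demes <- function(ds, marly = "Marly", bruenisried = "Bruenisried") {
  pop <- ds$metadata$population
  spot <- ds$metadata$spot
  lab <- rep(NA_character_, length(pop))
  lab[!is.na(pop) & pop == bruenisried] <- "Br"
  lab[!is.na(pop) & pop == marly & !is.na(spot) & grepl("#1", spot)] <- "Ma1"
  lab[!is.na(pop) & pop == marly & !is.na(spot) & grepl("#2", spot)] <- "Ma2"
  keep <- !is.na(lab)
  out <- subset_dataset(ds, specimens = keep)
  out$metadata$population <- lab[keep]
  out
}
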