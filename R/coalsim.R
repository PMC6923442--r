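#' Microsatellite mutation model configuration
#'
#' Generalized stepwise mutation (GSM): each mutation shifts the repeat
#' number by +/- s with s-1 geometric(P); `gsm_p = 0` is the strict
#' single-step model.  Per-locus rates are Gamma-distributed around the
#' mean rate (shape `rate_shape`), drawn once per simulated dataset.
#' Allele states are truncated to `range`; the wide default makes
#' truncation effectively inactive.
#'
#' @param mu_mean mean mutation rate per locus per generation; `NULL`
#'   means the value is taken from the parameter vector (`mu_mean`).
#' @param rate_shape Gamma shape of across-locus rate heterogeneity
#'   (rates are `mu_mean * Gamma(shape, scale = 1/shape)`); `Inf` gives
#'   equal rates.
#' @param gsm_p geometric step parameter in \[0, 1); `NULL` reads
#'   `gsm_p` from the parameter vector.
#' @param root root repeat number.
#' @param range allele bounds (repeat numbers).
#' @return a `mutation_model` list.
#' @export
mutation_model <- function(mu_mean = NULL, rate_shape = 2, gsm_p = NULL,
                           root = 100L, range = c(10L, 190L)) {
  stopifnot(is.null(gsm_p) || (gsm_p >= 0 && gsm_p < 1))
  structure(list(mu_mean = mu_mean, rate_shape = rate_shape,
                 gsm_p = gsm_p, root = as.integer(root),
                 range = as.integer(range)),
            class = "mutation_model")
}

# bind a scenario + parameter vector into the C++ demography encoding
.compile_demography <- function(scenario, params, sample_config) {
  demes <- scenario$demes
  sampled <- names(sample_config)
  if (!all(sampled %in% demes))
    stop("sample_config names must be scenario demes")
  val <- function(sym) {
    v <- suppressWarnings(as.numeric(sym))
    if (!is.na(v)) return(v)
    if (!sym %in% names(params)) stop("unbound symbol in scenario: ", sym)
    as.numeric(params[[sym]])
  }
  di <- stats::setNames(seq_along(demes) - 1L, demes)
  sizes <- list(); merges <- list()
  for (d in demes)
    sizes[[length(sizes) + 1]] <- c(di[[d]], 0, val(scenario$sizes[[d]]))
  ev <- scenario$events
  for (i in seq_len(nrow(ev))) {
    t <- val(ev$time[i]); nb <- val(ev$founder[i]); db <- val(ev$duration[i])
    d <- ev$derived[i]
    bstart <- max(t - db, 0)
    sizes[[length(sizes) + 1]] <- c(di[[d]], bstart, nb)
    merges[[length(merges) + 1]] <- c(t, di[[d]], di[[ev$source[i]]])
  }
  merges <- if (length(merges)) do.call(rbind, merges)
            else matrix(numeric(0), 0, 3)
  merges <- merges[order(merges[, 1]), , drop = FALSE]
  samples <- integer(length(demes))
  samples[di[sampled] + 1L] <- as.integer(sample_config)
  list(samples = samples, sizes = do.call(rbind, sizes),
       merges = merges, demes = demes, sampled = sampled)
}

#' Simulate a genotype dataset under a demographic scenario
#'
#' Per locus, an independent coalescent of the sampled gene copies is
#' run backwards through the scenario's piecewise-constant deme sizes,
#' founder bottlenecks and founding transfers, then mutations are laid
#' Poisson along branches under the generalized stepwise model.
#'
#' @param scenario a `demographic_scenario` (see [parse_scenario()]).
#' @param params named vector/list binding every scenario symbol (and,
#'   unless fixed in `mutation`, `mu_mean` and `gsm_p`).
#' @param sample_config named integer vector: diploids sampled per deme
#'   (all > 0).
#' @param n_loci number of independent loci.
#' @param mutation a [mutation_model()].
#' @param seed RNG seed.
#' @return a [genotype_dataset()] with deme names as populations.
#' @export
simulate_dataset <- function(scenario, params, sample_config,
                             n_loci = 13, mutation = mutation_model(),
                             seed = NULL) {
  if (any(sample_config <= 0)) stop("sample sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  cmp <- .compile_demography(scenario, params, sample_config)
  mu_mean <- mutation$mu_mean %||% params[["mu_mean"]]
  gsm_p <- mutation$gsm_p %||% params[["gsm_p"]]
  if (is.null(mu_mean) || is.null(gsm_p) || is.na(mu_mean) || is.na(gsm_p))
    stop("mu_mean and gsm_p must come from the mutation model or params")
  mu <- if (is.finite(mutation$rate_shape))
    mu_mean * rgamma(n_loci, shape = mutation$rate_shape,
                     scale = 1 / mutation$rate_shape)
  else rep(mu_mean, n_loci)
  g <- .coalsim_cpp(cmp$samples, cmp$sizes, cmp$merges, mu,
                    gsm_p, mutation$root,
                    mutation$range[1], mutation$range[2])
  a1 <- g[, seq(1, 2 * n_loci, 2), drop = FALSE]
  a2 <- g[, seq(2, 2 * n_loci, 2), drop = FALSE]
  pop <- rep(cmp$demes, cmp$samples)
  genotype_dataset(a1, a2, sprintf("sim%04d", seq_len(nrow(g))),
                   sprintf("SSR%02d", seq_len(n_loci)),
                   data.frame(population = pop, stringsAsFactors = FALSE))
}

#' Summary statistics for ABC on a genotype dataset
#'
#' Per deme: mean number of alleles, mean unbiased gene diversity, mean
#' allele-size variance, mean Garza-Williamson M (allele count over
#' allele-size span + 1).  Per deme pair: multilocus Weir-Cockerham
#' F_ST, shared-allele distance (`1 - sum_a min(p_A, p_B)` averaged over
#' loci) and the squared difference in mean allele size `(delta mu)^2`
#' averaged over loci.  The vector layout is fixed:
#' `4 * n_demes + 3 * n_pairs` values, demes in partition order, pairs
#' in column-major upper-triangle order.
#'
#' @param ds a [genotype_dataset()] with populations as demes.
#' @param demes deme names (default: the dataset's populations).
#' @return named numeric vector.
#' @export
compute_sumstats <- function(ds, demes = NULL) {
  if (is.null(demes)) demes <- population_partition(ds)$names
  if (length(demes) < 2) stop("need >= 2 demes for pairwise statistics")
  idx <- lapply(demes, function(p) .pop_idx(ds, p))
  .sumstats_idx(ds$a1, ds$a2, idx, demes)
}

.sumstats_idx <- function(a1, a2, idx, demes) {
  deme <- integer(nrow(a1))
  for (d in seq_along(idx)) deme[idx[[d]]] <- d
  keep <- deme > 0
  st <- .sumstats_cpp(a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                      deme[keep], length(idx))
  D <- length(demes)
  pair_names <- c()
  for (i in seq_len(D - 1)) for (j in seq((i + 1), D))
    pair_names <- c(pair_names,
                    paste0(c("fst.", "das.", "dmu2."),
                           demes[i], "_", demes[j]))
  names(st) <- c(as.vector(t(outer(demes, c("na", "hexp", "vsize", "gw"),
                                   function(d, s) paste0(s, ".", d)))),
                 pair_names)
  st
}

# reference R implementation of the same statistics (used as an
# independent cross-check in the test suite)
.sumstats_idx_r <- function(a1, a2, idx, demes) {
  D <- length(idx); L <- ncol(a1)
  per <- matrix(NA_real_, D, 4)
  freqs <- vector("list", D)
  means <- matrix(NA_real_, D, L)
  for (d in seq_len(D)) {
    na <- hx <- vs <- gw <- numeric(L)
    fl <- vector("list", L)
    for (l in seq_len(L)) {
      x <- c(a1[idx[[d]], l], a2[idx[[d]], l])
      x <- x[!is.na(x)]
      tab <- table(x)
      k <- length(tab); n2 <- length(x)
      p <- as.numeric(tab) / n2
      na[l] <- k
      hx[l] <- if (n2 > 1) (n2 / (n2 - 1)) * (1 - sum(p^2)) else 0
      vs[l] <- if (n2 > 1) var(x) else 0
      gw[l] <- k / (diff(range(x)) + 1)
      fl[[l]] <- tab / n2
      means[d, l] <- mean(x)
    }
    per[d, ] <- c(mean(na), mean(hx), mean(vs), mean(gw))
    freqs[[d]] <- fl
  }
  pair_stats <- c()
  pair_names <- c()
  for (i in seq_len(D - 1)) for (j in seq((i + 1), D)) {
    num <- 0; den <- 0
    das <- 0; dmu <- 0
    g <- rep(1:2, c(length(idx[[i]]), length(idx[[j]])))
    for (l in seq_len(L)) {
      comp <- .wc_locus(c(a1[idx[[i]], l], a1[idx[[j]], l]),
                        c(a2[idx[[i]], l], a2[idx[[j]], l]), g)
      if (!is.null(comp)) {
        num <- num + sum(comp[, "a"]); den <- den + sum(comp)
      }
      pi <- freqs[[i]][[l]]; pj <- freqs[[j]][[l]]
      shared <- intersect(names(pi), names(pj))
      das <- das + (1 - sum(pmin(pi[shared], pj[shared])))
      dmu <- dmu + (means[i, l] - means[j, l])^2
    }
    theta <- if (den > 0) num / den else 0
    pair_stats <- c(pair_stats, theta, das / L, dmu / L)
    pair_names <- c(pair_names,
                    paste0(c("fst.", "das.", "dmu2."),
                           demes[i], "_", demes[j]))
  }
  out <- c(t(per), pair_stats)
  names(out) <- c(as.vector(t(outer(demes, c("na", "hexp", "vsize", "gw"),
                                    function(d, s) paste0(s, ".", d)))),
                  pair_names)
  out
}
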