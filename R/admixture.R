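#' Bayesian admixture clustering of multilocus genotypes
#'
#' STRUCTURE-style Gibbs sampler under the admixture model with
#' correlated allele frequencies (F-model): each allele copy carries a
#' latent cluster origin, individuals have Dirichlet(alpha) admixture
#' proportions with a single alpha shared across specimens
#' (uniform(0, `alpha_max`) hyperprior, Metropolis update), and cluster
#' allele frequencies are tied to the empirical mean frequencies through
#' per-cluster drift parameters F_k (uniform(0,1) prior).  No location
#' prior is used.  Missing calls are skipped in the likelihood.
#'
#' @param ds a [genotype_dataset()] with at least one polymorphic locus.
#' @param K number of clusters (>= 1).
#' @param seed RNG seed; runs are bit-reproducible given seed and config.
#' @param burnin,iters burn-in and retained MCMC sweeps (defaults
#'   20000/20000 are desk-scale; scale up for production runs).
#' @param thin trace thinning interval.
#' @param model_config list of prior settings: `alpha_init` (0.5),
#'   `alpha_max` (10), `alpha_step` (0.05), `f_step` (0.05).
#' @return a `structure_run`: `K`, `q` (specimen x K posterior-mean
#'   admixture, rows sum to 1), `p` (per locus cluster x allele
#'   posterior-mean frequencies), `loglik_trace`, `alpha_trace`,
#'   `f_trace`, `lnpk` (the model-evidence estimate, see
#'   [estimate_lnpk()]), `seed`, `burnin`, `iters`, `nonmixing` flag.
#' @export
structure_run <- function(ds, K, seed = 1L, burnin = 20000, iters = 20000,
                          thin = 10, model_config = list()) {
  stopifnot(K >= 1, iters >= thin)
  cfg <- modifyList(list(alpha_init = 0.5, alpha_max = 10,
                         alpha_step = 0.05, f_step = 0.05), model_config)
  enc <- .encode_for_structure(ds)
  if (all(enc$n_alleles <= 1L))
    stop("dataset has no polymorphic locus")
  set.seed(seed)
  res <- .structure_gibbs_cpp(enc$geno, enc$n_alleles, as.integer(K),
                              as.integer(burnin), as.integer(iters),
                              as.integer(thin),
                              cfg$alpha_init, cfg$alpha_max,
                              cfg$alpha_step, cfg$f_step)
  rownames(res$q) <- ds$specimen_ids
  colnames(res$q) <- paste0("K", seq_len(K))
  names(res$p) <- ds$loci
  tr <- res$loglik_trace
  # crude non-mixing diagnostic: strong monotone trend in the kept trace
  nonmix <- FALSE
  if (length(tr) > 10) {
    rho <- suppressWarnings(cor(seq_along(tr), tr, method = "spearman"))
    nonmix <- is.finite(rho) && abs(rho) > 0.6
    if (nonmix)
      warning("log-likelihood trace still trending (rho = ",
              round(rho, 2), "); consider a longer burn-in")
  }
  out <- list(K = K, q = res$q, p = res$p,
              loglik_trace = tr, alpha_trace = res$alpha_trace,
              f_trace = res$f_trace, seed = seed,
              burnin = burnin, iters = iters, thin = thin,
              nonmixing = nonmix)
  out$lnpk <- estimate_lnpk(out)
  class(out) <- "structure_run"
  out
}

#' @export
print.structure_run <- function(x, ...) {
  cat("structure_run: K =", x$K, " lnP(X|K) =", round(x$lnpk, 1),
      " (", length(x$loglik_trace), "samples )\n")
  invisible(x)
}

.encode_for_structure <- function(ds) {
  n <- n_specimens(ds); L <- n_loci(ds)
  geno <- matrix(-1L, n, 2L * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(ds$a1[, l], ds$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    n_alleles[l] <- max(1L, length(alleles))
    i1 <- match(ds$a1[, l], alleles) - 1L
    i2 <- match(ds$a2[, l], alleles) - 1L
    i1[is.na(i1)] <- -1L; i2[is.na(i2)] <- -1L
    geno[, 2L * l - 1L] <- i1
    geno[, 2L * l] <- i2
  }
  list(geno = geno, n_alleles = n_alleles)
}

#' Model-evidence estimate ln P(X|K) from a run's likelihood trace
#'
#' The STRUCTURE estimator: mean of the post-burn-in log-likelihood
#' trace minus half its sample variance (n-1 denominator).
#'
#' @param run a `structure_run`, or any list with a `loglik_trace`.
#' @return scalar estimate.
#' @export
estimate_lnpk <- function(run) {
  tr <- run$loglik_trace
  if (length(tr) < 2) stop("log-likelihood trace needs >= 2 samples")
  mean(tr) - var(tr) / 2
}

#' Evanno Delta-K table from ln P(X|K) estimates over runs
#'
#' For each interior K: `L'(K) = mean(K) - mean(K-1)`,
#' `L''(K) = |L'(K+1) - L'(K)|`, `DeltaK = L''(K) / SD(K)`.  The K
#' maximizing DeltaK is reported; K values with zero run-to-run SD have
#' undefined DeltaK and are excluded from the argmax with a warning.
#'
#' @param lnpk_by_k named list: names are consecutive K values, each
#'   element the per-run ln P(X|K) estimates (>= 2 runs).
#' @return data.frame of class `evanno_table` with columns `K`, `mean`,
#'   `sd`, `lprime`, `lsecond`, `delta_k`, and attribute `best_k`.
#' @export
evanno <- function(lnpk_by_k) {
  Ks <- as.integer(names(lnpk_by_k))
  if (length(Ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  if (any(lengths(lnpk_by_k) < 2)) stop("need >= 2 runs per K")
  mu <- vapply(lnpk_by_k, mean, numeric(1))
  sdv <- vapply(lnpk_by_k, sd, numeric(1))
  m <- length(Ks)
  lprime <- c(NA, diff(mu))                       # L'(K), defined K>=2
  lsecond <- rep(NA_real_, m)
  for (j in 2:(m - 1)) lsecond[j] <- abs(lprime[j + 1] - lprime[j])
  delta <- lsecond / sdv
  if (any(sdv == 0 & !is.na(lsecond)))
    warning("zero run-to-run SD at K = ",
            paste(Ks[sdv == 0 & !is.na(lsecond)], collapse = ", "),
            "; DeltaK undefined there")
  delta[sdv == 0] <- NA_real_
  out <- data.frame(K = Ks, mean = mu, sd = sdv, lprime = lprime,
                    lsecond = lsecond, delta_k = delta,
                    row.names = NULL)
  attr(out, "best_k") <-
    if (all(is.na(delta))) NA_integer_ else Ks[which.max(delta)]
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Align admixture runs by greedy cluster matching and average them
#'
#' Cluster labels are arbitrary within each run.  Using the run with the
#' highest ln P(X|K) as reference, each other run's columns are matched
#' greedily (best remaining column pair by squared-error similarity,
#' CLUMPP's greedy strategy), then the aligned membership matrices are
#' averaged.
#'
#' @param runs list of `structure_run` objects (same K, same specimens),
#'   or plain q matrices.
#' @return the averaged specimen x cluster `QMatrix` (rows sum to 1),
#'   with attribute `permutations` (list of the column orders applied).
#' @export
align_runs_greedy <- function(runs) {
  qs <- lapply(runs, function(r) if (is.list(r)) r$q else r)
  K <- ncol(qs[[1]])
  if (any(vapply(qs, ncol, integer(1)) != K))
    stop("all runs must share K")
  if (length(runs) == 1L || K == 1L) {
    out <- Reduce(`+`, qs) / length(qs)
    attr(out, "permutations") <- rep(list(seq_len(K)), length(qs))
    return(out)
  }
  lnp <- vapply(runs, function(r)
    if (is.list(r) && !is.null(r$lnpk)) r$lnpk else NA_real_, numeric(1))
  ref_i <- if (all(is.na(lnp))) 1L else which.max(lnp)
  ref <- qs[[ref_i]]
  perms <- vector("list", length(qs))
  acc <- matrix(0, nrow(ref), K)
  for (j in seq_along(qs)) {
    if (j == ref_i) { perms[[j]] <- seq_len(K); acc <- acc + ref; next }
    qj <- qs[[j]]
    # similarity: negative SSE between reference column and candidate
    sim <- -vapply(seq_len(K), function(b)
      vapply(seq_len(K), function(a) sum((ref[, a] - qj[, b])^2),
             numeric(1)), numeric(K))   # sim[a, b]
    perm <- integer(K)
    free_a <- rep(TRUE, K); free_b <- rep(TRUE, K)
    for (s in seq_len(K)) {
      w <- which(sim == max(sim[free_a, free_b, drop = FALSE]), arr.ind = TRUE)
      w <- w[free_a[w[, 1]] & free_b[w[, 2]], , drop = FALSE][1, ]
      perm[w[1]] <- w[2]
      free_a[w[1]] <- FALSE; free_b[w[2]] <- FALSE
      sim[w[1], ] <- -Inf; sim[, w[2]] <- -Inf
    }
    perms[[j]] <- perm
    acc <- acc + qj[, perm, drop = FALSE]
  }
  out <- acc / length(qs)
  out <- out / rowSums(out)
  dimnames(out) <- dimnames(ref)
  attr(out, "permutations") <- perms
  out
}

#' Run the admixture sampler over a K grid with replicate runs
#'
#' @param ds a [genotype_dataset()].
#' @param k_values integer vector of K values (consecutive for Evanno).
#' @param n_runs replicate runs per K.
#' @param seed base seed; run r at K uses `seed + 1000*K + r`.
#' @param ... passed to [structure_run()] (burnin, iters, thin,
#'   model_config).
#' @return list with `runs` (nested list), `lnpk` (list by K),
#'   `evanno` (when >= 3 consecutive K), `q_aligned` (averaged QMatrix
#'   per K), and `assignment_diagnostic` (per K, max membership peak of
#'   each cluster — low peaks suggest superfluous clusters).
#' @export
structure_kscan <- function(ds, k_values = 1:6, n_runs = 3, seed = 1L,
                            ...) {
  runs <- lapply(k_values, function(K)
    lapply(seq_len(n_runs), function(r)
      structure_run(ds, K, seed = seed + 1000L * K + r, ...)))
  names(runs) <- k_values
  lnpk <- lapply(runs, vapply, estimate_lnpk, numeric(1))
  ev <- NULL
  if (length(k_values) >= 3 && all(diff(k_values) == 1) && n_runs >= 2)
    ev <- evanno(lnpk)
  qa <- lapply(runs, align_runs_greedy)
  diag_peak <- lapply(qa, function(q) apply(q, 2, max))
  list(runs = runs, lnpk = lnpk, evanno = ev, q_aligned = qa,
       assignment_diagnostic = diag_peak)
}

#' Admixture barplot of a Q matrix
#'
#' @param qmat specimen x cluster matrix (rows sum to 1).
#' @param populations optional specimen grouping used to order the bars.
#' @return a ggplot object.
#' @export
plot_structure_barplot <- function(qmat, populations = NULL) {
  ord <- seq_len(nrow(qmat))
  if (!is.null(populations)) ord <- order(populations, -qmat[, 1])
  df <- data.frame(
    specimen = rep(factor(ord, levels = ord), ncol(qmat)),
    cluster = rep(colnames(qmat) %||% paste0("K", seq_len(ncol(qmat))),
                  each = nrow(qmat)),
    q = as.vector(qmat[ord, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = specimen, y = q, fill = cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
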