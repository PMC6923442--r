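#' Build an ABC reference table of simulated summary statistics
#'
#' For each scenario, draws parameters from the priors (respecting the
#' scenario's own order constraints), simulates a dataset of the
#' observed sample configuration, and records the summary-statistic
#' vector.  Row `i` uses seed `seed + i`, so the table is deterministic
#' regardless of evaluation order.
#'
#' @param scenarios named list of `demographic_scenario` objects.
#' @param priors a [prior_spec()].
#' @param n_per_scenario simulations per scenario.
#' @param sample_config named diploid sample sizes per sampled deme.
#' @param n_loci loci per simulated dataset.
#' @param mutation a [mutation_model()].
#' @param seed base seed.
#' @return a `reference_table`: `scenario` (factor), `params`
#'   (data.frame), `stats` (matrix), plus the generating configuration.
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario,
                                  sample_config, n_loci = 13,
                                  mutation = mutation_model(),
                                  seed = 1L) {
  if (length(scenarios) < 1) stop("need at least one scenario")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  demes <- names(sample_config)
  rows_sc <- character(0)
  params_list <- list(); stats_list <- list()
  row <- 0L
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    pr <- prior_spec(priors$params,
                     unique(c(priors$constraints, sc$constraints)))
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      set.seed(seed + row)
      par <- sample_prior(pr, 1)
      ds <- simulate_dataset(sc, as.list(par), sample_config,
                             n_loci = n_loci, mutation = mutation)
      st <- .sumstats_idx(ds$a1, ds$a2,
                          lapply(demes, function(d)
                            which(ds$metadata$population == d)),
                          demes)
      rows_sc <- c(rows_sc, sc_name)
      params_list[[row]] <- par
      stats_list[[row]] <- st
    }
  }
  structure(list(
    scenario = factor(rows_sc, levels = names(scenarios)),
    params = do.call(rbind, params_list),
    stats = do.call(rbind, stats_list),
    priors = priors, sample_config = sample_config,
    n_loci = n_loci, mutation = mutation, seed = seed),
    class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table:", nrow(x$stats), "rows,",
      nlevels(x$scenario), "scenarios,", ncol(x$stats), "statistics\n")
  invisible(x)
}

# standardize stats by reference-table SDs; returns list with scaled
# table, scaled observed, kept columns
.standardize_stats <- function(table_stats, observed) {
  sds <- apply(table_stats, 2, sd)
  keep <- sds > 0
  if (any(!keep))
    warning("dropping zero-variance statistics: ",
            paste(colnames(table_stats)[!keep], collapse = ", "))
  ctr <- colMeans(table_stats[, keep, drop = FALSE])
  list(tab = scale(table_stats[, keep, drop = FALSE], ctr, sds[keep]),
       obs = (observed[keep] - ctr) / sds[keep],
       keep = keep)
}

#' Direct ABC scenario choice from the closest simulations
#'
#' Statistics are standardized by the reference-table SDs; the posterior
#' probability of each scenario is its share among the `n_closest`
#' simulations by Euclidean distance to the observed vector, with a
#' binomial normal-approximation confidence interval.
#'
#' @param observed_stats named statistic vector (see
#'   [compute_sumstats()]).
#' @param table a `reference_table`.
#' @param n_closest number of retained simulations (default 500).
#' @return an `abc_selection`: data.frame `posterior` (scenario,
#'   probability, ci_lo, ci_hi), `method = "direct"`, `n_closest`.
#' @export
select_scenario_direct <- function(observed_stats, table,
                                   n_closest = 500) {
  stopifnot(n_closest <= nrow(table$stats))
  z <- .standardize_stats(table$stats, observed_stats)
  d <- sqrt(rowSums(sweep(z$tab, 2, z$obs)^2))
  sel <- order(d)[seq_len(n_closest)]
  shares <- table(table$scenario[sel]) / n_closest
  p <- as.numeric(shares)
  se <- sqrt(p * (1 - p) / n_closest)
  out <- data.frame(scenario = names(shares), probability = p,
                    ci_lo = pmax(0, p - 1.96 * se),
                    ci_hi = pmin(1, p + 1.96 * se),
                    stringsAsFactors = FALSE)
  structure(list(posterior = out, method = "direct",
                 n_closest = n_closest,
                 best = out$scenario[which.max(out$probability)]),
            class = "abc_selection")
}

#' @export
print.abc_selection <- function(x, ...) {
  cat("ABC scenario choice (", x$method, "):\n", sep = "")
  print(x$posterior, row.names = FALSE)
  invisible(x)
}

#' LDA + multinomial-logistic ABC scenario choice
#'
#' Fits a linear discriminant transformation of the standardized summary
#' statistics on the scenario labels of the full reference table, then a
#' weighted multinomial logistic regression of the label on the
#' discriminant coordinates over the closest `fraction` of simulations
#' (Epanechnikov weights in the standardized distance), evaluated at the
#' observed point.  Confidence intervals come from the regression
#' coefficient covariance by the delta method.
#'
#' @param observed_stats named statistic vector.
#' @param table a `reference_table` with >= 2 scenarios.
#' @param fraction fraction of closest simulations used in the
#'   regression (default 0.01).
#' @return an `abc_selection` with `method = "lda-logistic"`.
#' @export
select_scenario_lda_logistic <- function(observed_stats, table,
                                         fraction = 0.01) {
  if (nlevels(droplevels(table$scenario)) < 2)
    stop("need >= 2 scenarios in the reference table")
  z <- .standardize_stats(table$stats, observed_stats)
  d <- sqrt(rowSums(sweep(z$tab, 2, z$obs)^2))
  n_keep <- max(2L, ceiling(fraction * nrow(z$tab)))
  sel <- order(d)[seq_len(n_keep)]
  lev <- levels(table$scenario)
  present <- lev[lev %in% unique(as.character(table$scenario[sel]))]
  if (length(present) < length(lev))
    warning("scenarios absent from the closest set get probability 0: ",
            paste(setdiff(lev, present), collapse = ", "))
  if (length(present) < 2) {
    p <- as.numeric(lev %in% present)
    out <- data.frame(scenario = lev, probability = p,
                      ci_lo = p, ci_hi = p, stringsAsFactors = FALSE)
    return(structure(list(posterior = out, method = "lda-logistic",
                          fraction = fraction,
                          best = out$scenario[which.max(p)]),
                     class = "abc_selection"))
  }
  ld <- MASS::lda(z$tab, grouping = table$scenario)
  lx <- z$tab %*% ld$scaling
  lobs <- matrix(z$obs, 1) %*% ld$scaling
  dmax <- max(d[sel])
  w <- 1 - (d[sel] / (dmax * (1 + 1e-9)))^2
  df <- data.frame(y = droplevels(table$scenario[sel]),
                   lx[sel, , drop = FALSE])
  fit <- nnet::multinom(y ~ ., data = df, weights = w, trace = FALSE,
                        Hess = TRUE, maxit = 300)
  newd <- as.data.frame(lobs)
  colnames(newd) <- colnames(lx)
  pr <- predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) {           # two-class case returns P(class 2)
    pr <- c(1 - pr, pr)
    names(pr) <- fit$lev
  }
  # delta-method CI on the predicted probabilities: vcov(multinom) is
  # class-major, i.e. all coefficients of class 2, then class 3, ...
  se <- rep(NA_real_, length(pr))
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(vc)) {
    cfm0 <- coef(fit)
    bvec <- if (is.null(dim(cfm0))) as.numeric(cfm0)
            else as.numeric(t(cfm0))
    X <- c(1, as.numeric(lobs))
    predfun <- function(b) {
      cfm <- matrix(b, ncol = length(X), byrow = TRUE)
      ex <- c(1, exp(cfm %*% X))
      ex / sum(ex)
    }
    eps <- 1e-5
    J <- vapply(seq_along(bvec), function(j) {
      bp <- bvec; bp[j] <- bp[j] + eps
      bm <- bvec; bm[j] <- bm[j] - eps
      (predfun(bp) - predfun(bm)) / (2 * eps)
    }, numeric(length(pr)))
    if (all(dim(vc) == c(length(bvec), length(bvec))))
      se <- sqrt(pmax(0, diag(J %*% vc %*% t(J))))
  }
  p_full <- stats::setNames(rep(0, length(lev)), lev)
  p_full[names(pr)] <- pmax(as.numeric(pr), 0)
  p_full <- p_full / sum(p_full)
  se_full <- stats::setNames(rep(0, length(lev)), lev)
  se_full[names(pr)] <- se
  out <- data.frame(scenario = lev, probability = as.numeric(p_full),
                    ci_lo = pmax(0, p_full - 1.96 * se_full),
                    ci_hi = pmin(1, p_full + 1.96 * se_full),
                    stringsAsFactors = FALSE)
  structure(list(posterior = out, method = "lda-logistic",
                 fraction = fraction,
                 best = out$scenario[which.max(out$probability)]),
            class = "abc_selection")
}

#' Local-linear ABC parameter estimation for one scenario
#'
#' Takes the closest `fraction` of the (single-scenario) reference
#' table, logit-transforms each parameter to its prior bounds, adjusts
#' by weighted local-linear regression on the standardized statistics
#' (Epanechnikov weights), and back-transforms.  The kernel-density mode
#' and the median summarize the adjusted sample (the regression removes
#' most of the neighbourhood's prior spread, sharpening point
#' estimates); the 2.5/97.5% credible bounds are taken from the
#' *unadjusted* (rejection) sample of the same neighbourhood, which is
#' calibrated at moderate table sizes where the linear adjustment is
#' anti-conservative.  The logit transform guarantees all estimates and
#' draws inside the prior support.
#'
#' @param observed_stats named statistic vector.
#' @param table a `reference_table` restricted to one scenario (or with
#'   a single scenario level present).
#' @param fraction closest fraction retained (default 0.01; at least 50
#'   rows are required).
#' @param parameters parameter names to estimate (default: all).
#' @param min_rows neighbourhood floor: at least this many rows are
#'   retained when the table allows it (default 300).  Very small
#'   neighbourhoods make the regression residuals, and hence the
#'   credible-interval quantiles, unstable.
#' @return an `abc_estimate`: data.frame `summary` (parameter, mode,
#'   median, q025, q975) and matrix `adjusted` of posterior draws.
#' @export
estimate_parameters <- function(observed_stats, table, fraction = 0.01,
                                parameters = NULL, min_rows = 300) {
  if (nlevels(droplevels(factor(table$scenario))) != 1)
    stop("reference table must be restricted to a single scenario")
  z <- .standardize_stats(table$stats, observed_stats)
  d <- sqrt(rowSums(sweep(z$tab, 2, z$obs)^2))
  n_keep <- max(ceiling(fraction * nrow(z$tab)),
                min(min_rows, nrow(z$tab)))
  if (n_keep < 50)
    stop("closest fraction keeps ", n_keep,
         " rows (< 50); enlarge the table or the fraction")
  sel <- order(d)[seq_len(n_keep)]
  dmax <- max(d[sel])
  w <- 1 - (d[sel] / (dmax * (1 + 1e-9)))^2
  if (is.null(parameters)) parameters <- colnames(table$params)
  X <- z$tab[sel, , drop = FALSE]
  adj <- list(); summ <- list()
  for (pm in parameters) {
    x <- table$params[sel, pm]
    pr <- table$priors$params[[pm]]
    lo <- pr$min; hi <- pr$max
    eps <- (hi - lo) * 1e-9
    xt <- log((x - lo + eps) / (hi - x + eps))
    fit <- lm(xt ~ X, weights = w)
    pred_obs <- sum(coef(fit) * c(1, z$obs), na.rm = TRUE)
    xadj_t <- pred_obs + residuals(fit)
    xadj <- lo + (hi - lo) / (1 + exp(-xadj_t))
    adj[[pm]] <- xadj
    dens <- density(xadj, n = 512)
    summ[[pm]] <- data.frame(
      parameter = pm, mode = dens$x[which.max(dens$y)],
      median = median(xadj),
      q025 = quantile(x, 0.025, names = FALSE),
      q975 = quantile(x, 0.975, names = FALSE))
  }
  structure(list(summary = do.call(rbind, summ),
                 adjusted = do.call(cbind, adj),
                 n_closest = n_keep),
            class = "abc_estimate")
}

# interpolated weighted quantiles
.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' @export
print.abc_estimate <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Type-I / type-II error of a chosen scenario
#'
#' Treats `n_pods` held-out reference-table rows per scenario as
#' pseudo-observed datasets, reruns scenario choice on each against the
#' remaining rows, and reports the rate at which the chosen scenario is
#' missed on its own PODs (type I) and selected on other scenarios'
#' PODs (type II).
#'
#' @param table a `reference_table` covering all scenarios.
#' @param chosen_scenario scenario name.
#' @param n_pods PODs per scenario.
#' @param seed RNG seed for the held-out draw.
#' @param method `"direct"` (default) or `"lda-logistic"`.
#' @param n_closest retained simulations for the direct method.
#' @return list with `type1`, `type2`, `n_pods`.
#' @export
scenario_confidence <- function(table, chosen_scenario, n_pods = 100,
                                seed = 1L, method = "direct",
                                n_closest = 500) {
  lev <- levels(table$scenario)
  if (!chosen_scenario %in% lev) stop("unknown scenario")
  set.seed(seed)
  hold <- unlist(lapply(lev, function(s) {
    rows <- which(table$scenario == s)
    if (length(rows) <= n_pods)
      stop("n_pods exceeds available rows for scenario ", s)
    sample(rows, n_pods)
  }))
  rest <- table
  rest$scenario <- table$scenario[-hold]
  rest$params <- table$params[-hold, , drop = FALSE]
  rest$stats <- table$stats[-hold, , drop = FALSE]
  top <- vapply(hold, function(r) {
    obs <- table$stats[r, ]
    selres <- if (method == "direct")
      select_scenario_direct(obs, rest,
                             n_closest = min(n_closest, nrow(rest$stats)))
    else select_scenario_lda_logistic(obs, rest)
    selres$best
  }, character(1))
  truth <- as.character(table$scenario[hold])
  own <- truth == chosen_scenario
  list(type1 = mean(top[own] != chosen_scenario),
       type2 = mean(top[!own] == chosen_scenario),
       n_pods = n_pods)
}

#' Posterior-predictive simulations for goodness-of-fit
#'
#' Draws parameter vectors from the adjusted posterior sample of an
#' [estimate_parameters()] fit and simulates a dataset for each.
#'
#' @param scenario the fitted `demographic_scenario`.
#' @param estimate an `abc_estimate` for that scenario.
#' @param sample_config,n_loci,mutation as in [build_reference_table()].
#' @param n_sims number of predictive simulations.
#' @param seed base seed.
#' @return matrix of predictive summary-statistic vectors.
#' @export
simulate_posterior_predictive <- function(scenario, estimate,
                                          sample_config, n_loci = 13,
                                          mutation = mutation_model(),
                                          n_sims = 200, seed = 1L) {
  demes <- names(sample_config)
  adj <- estimate$adjusted
  out <- matrix(NA_real_, n_sims, 0)
  rows <- list()
  for (i in seq_len(n_sims)) {
    set.seed(seed + i)
    par <- as.list(adj[sample(nrow(adj), 1), ])
    ds <- simulate_dataset(scenario, par, sample_config,
                           n_loci = n_loci, mutation = mutation)
    rows[[i]] <- .sumstats_idx(ds$a1, ds$a2,
                               lapply(demes, function(d)
                                 which(ds$metadata$population == d)),
                               demes)
  }
  do.call(rbind, rows)
}

#' Goodness-of-fit of a scenario via posterior-predictive tail areas
#'
#' For each summary statistic, the two-sided tail probability of the
#' observed value within the predictive distribution (add-one
#' estimator, so never 0), plus a PCA overlay of the observed point on
#' the predictive cloud.
#'
#' @param observed_stats named statistic vector.
#' @param posterior_predictive_sims matrix from
#'   [simulate_posterior_predictive()] (>= 100 rows recommended).
#' @return list with `tails` (data.frame: statistic, p_tail, flagged
#'   degenerate statistics) and `pca` (scores of sims and observed).
#' @export
goodness_of_fit <- function(observed_stats, posterior_predictive_sims) {
  sims <- posterior_predictive_sims
  stopifnot(ncol(sims) == length(observed_stats))
  n <- nrow(sims)
  tails <- vapply(seq_along(observed_stats), function(j) {
    x <- sims[, j]
    if (sd(x) == 0) return(NA_real_)
    lo <- (1 + sum(x <= observed_stats[j])) / (n + 1)
    hi <- (1 + sum(x >= observed_stats[j])) / (n + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  degenerate <- vapply(seq_along(observed_stats), function(j)
    sd(sims[, j]) == 0, logical(1))
  keep <- !degenerate
  pc <- prcomp(sims[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  obs_score <- predict(pc, matrix(observed_stats[keep], 1,
                                  dimnames = list(NULL,
                                                  colnames(sims)[keep])))
  list(tails = data.frame(statistic = names(observed_stats),
                          p_tail = tails, degenerate = degenerate,
                          stringsAsFactors = FALSE),
       pca = list(sims = pc$x[, 1:2, drop = FALSE],
                  observed = obs_score[, 1:2, drop = FALSE]))
}

#' Simulate an outbreak dataset with a known generating truth
#'
#' Wraps [simulate_dataset()] and returns the generating scenario and
#' parameters alongside the data, optionally adding host-tree labels
#' (specimens of a deme split round-robin over trees).
#'
#' @param scenario a `demographic_scenario`.
#' @param params named parameter values (see [simulate_dataset()]).
#' @param sample_config named diploid sample sizes.
#' @param n_loci,mutation,seed as in [simulate_dataset()].
#' @param trees_per_deme optional integer; adds tree metadata.
#' @return list with `dataset` and `truth` (scenario, params).
#' @export
make_outbreak_dataset <- function(scenario, params, sample_config,
                                  n_loci = 13,
                                  mutation = mutation_model(),
                                  seed = 1L, trees_per_deme = 0) {
  ds <- simulate_dataset(scenario, params, sample_config,
                         n_loci = n_loci, mutation = mutation,
                         seed = seed)
  if (trees_per_deme > 0) {
    pop <- ds$metadata$population
    for (d in unique(pop)) {
      rows <- which(pop == d)
      ds$metadata$tree[rows] <-
        sprintf("%s_tree%02d", d,
                rep(seq_len(trees_per_deme), length.out = length(rows)))
    }
  }
  list(dataset = ds,
       truth = list(scenario = scenario, params = params,
                    sample_config = sample_config, seed = seed))
}
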