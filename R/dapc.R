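#' Cross-validated choice of the number of retained principal components
#'
#' Stratified k-fold cross-validation of DAPC assignment success over a
#' grid of candidate PC counts.  For each fold the PCA and the
#' discriminant analysis are fitted on the training specimens only and
#' the held-out specimens are assigned; the returned PC count maximizes
#' mean held-out correct-assignment rate (ties broken towards fewer PCs).
#'
#' @param matrix numeric specimen x variable matrix (see
#'   [encode_alleles()]).
#' @param groups factor/character of group labels (>= 2 groups).
#' @param folds number of folds (default 5); reduced with a warning when
#'   a group is smaller than the fold count.
#' @param candidate_pcs integer vector of PC counts to try (default
#'   `1:min(40, rank)`).
#' @param seed RNG seed for fold assignment.
#' @return list with `n_pcs` (the chosen count), and `success` (named mean
#'   held-out success per candidate).
#' @export
xval_n_pcs <- function(matrix, groups, folds = 5, candidate_pcs = NULL,
                       seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  min_g <- min(table(groups))
  if (min_g < folds) {
    warning("smallest group (", min_g, ") smaller than fold count; using ",
            max(2L, min_g), " folds")
    folds <- max(2L, min_g)
  }
  maxrank <- min(nrow(matrix) - folds, ncol(matrix))
  if (is.null(candidate_pcs)) candidate_pcs <- seq_len(min(40L, maxrank))
  candidate_pcs <- candidate_pcs[candidate_pcs <= maxrank]
  set.seed(seed)
  fold_of <- integer(nrow(matrix))
  for (g in levels(groups)) {
    i <- which(groups == g)
    fold_of[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  }
  succ <- sapply(candidate_pcs, function(npc) {
    ok <- 0L; tot <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f; te <- !tr
      fit <- try(dapc_fit(matrix[tr, , drop = FALSE], groups[tr], npc),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      pred <- predict_dapc(fit, matrix[te, , drop = FALSE])
      ok <- ok + sum(pred$assigned == as.character(groups[te]))
      tot <- tot + sum(te)
    }
    if (tot == 0L) return(NA_real_)
    ok / tot
  })
  names(succ) <- candidate_pcs
  best <- candidate_pcs[which.max(succ)]   # which.max takes first tie
  list(n_pcs = best, success = succ)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the (centered, unscaled) data to `n_pcs` principal components,
#' then fits a canonical linear discriminant analysis of the predefined
#' groups on the retained PCs.  Posterior group membership comes from the
#' Gaussian class model in discriminant space.  Axis signs are fixed by
#' forcing the largest-magnitude variable loading positive on each
#' discriminant axis, so coordinates are reproducible up to data order.
#'
#' @param matrix numeric specimen x variable matrix.
#' @param groups factor/character group labels.
#' @param n_pcs number of principal components to retain (<= rank).
#' @return a `dapc_model` list: `n_pcs_retained`, `group_labels`,
#'   `specimen_coords` (LD axes), `posterior` (rows sum to 1),
#'   `assigned`, `discriminant_axes` (loadings on the original
#'   variables), `var_explained`, plus internal projection terms.
#' @export
dapc_fit <- function(matrix, groups, n_pcs) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ctr <- colMeans(matrix)
  pc <- prcomp(matrix, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-9)
  if (n_pcs > rank) stop("n_pcs (", n_pcs, ") exceeds rank (", rank, ")")
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- tryCatch(
    MASS::lda(scores, grouping = groups),
    error = function(e) {
      # singular within-group covariance: ridge fallback on the scores
      message("within-group covariance singular; adding ridge")
      MASS::lda(scores + matrix(rnorm(length(scores), sd = 1e-8),
                                nrow(scores)), grouping = groups)
    })
  ld <- scores %*% fit$scaling
  # loadings on original variables, with deterministic axis signs
  axes <- pc$rotation[, seq_len(n_pcs), drop = FALSE] %*% fit$scaling
  sgn <- apply(axes, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  axes <- sweep(axes, 2, sgn, `*`)
  ld <- sweep(ld, 2, sgn, `*`)
  post <- predict(fit, scores)$posterior
  structure(list(
    n_pcs_retained = n_pcs,
    group_labels = levels(groups),
    specimen_coords = ld,
    posterior = post,
    assigned = as.character(predict(fit, scores)$class),
    discriminant_axes = axes,
    var_explained = fit$svd^2 / sum(fit$svd^2),
    center = ctr, rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
    lda = fit, sign = sgn), class = "dapc_model")
}

#' Project new specimens onto a fitted DAPC model
#'
#' @param model a `dapc_model` from [dapc_fit()].
#' @param matrix new specimen x variable matrix (same columns as the
#'   training encoding).
#' @return list with `coords`, `posterior`, `assigned`.
#' @export
predict_dapc <- function(model, matrix) {
  scores <- sweep(matrix, 2, model$center) %*% model$rotation
  pr <- predict(model$lda, scores)
  coords <- sweep(scores %*% model$lda$scaling, 2, model$sign, `*`)
  list(coords = coords, posterior = pr$posterior,
       assigned = as.character(pr$class))
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("DAPC:", x$n_pcs_retained, "PCs,",
      length(x$group_labels), "groups,",
      ncol(x$specimen_coords), "discriminant axes\n")
  cat("mean self-assignment:",
      round(mean(vapply(seq_len(nrow(x$posterior)), function(i)
        x$posterior[i, x$assigned[i]], numeric(1))), 3), "\n")
  invisible(x)
}

#' Run DAPC on a genotype dataset grouped by population
#'
#' Convenience wrapper: dosage-encodes the dataset, optionally
#' cross-validates the PC count, and fits the DAPC on the population
#' labels (specimens without a label are dropped).
#'
#' @param ds a [genotype_dataset()].
#' @param n_pcs PC count; `NULL` (default) chooses by cross-validation.
#' @param folds cross-validation folds.
#' @param seed RNG seed.
#' @return a `dapc_model` with an added `xval` element when
#'   cross-validation ran.
#' @export
dapc_populations <- function(ds, n_pcs = NULL, folds = 5, seed = 1L) {
  keep <- !is.na(ds$metadata$population)
  dsk <- subset_dataset(ds, specimens = keep)
  m <- encode_alleles(dsk)
  g <- dsk$metadata$population
  xv <- NULL
  if (is.null(n_pcs)) {
    xv <- xval_n_pcs(m, g, folds = folds, seed = seed)
    n_pcs <- xv$n_pcs
  }
  fit <- dapc_fit(m, g, n_pcs)
  fit$xval <- xv
  fit
}

#' Scatter plot of the first two discriminant axes
#'
#' @param model a `dapc_model`.
#' @param groups optional group labels for coloring (defaults to the
#'   model's assignments).
#' @return a ggplot object.
#' @export
plot_dapc <- function(model, groups = NULL) {
  co <- model$specimen_coords
  if (ncol(co) < 2) stop("model has a single discriminant axis")
  df <- data.frame(LD1 = co[, 1], LD2 = co[, 2],
                   group = groups %||% model$assigned)
  ggplot2::ggplot(df, ggplot2::aes(x = LD1, y = LD2, colour = group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(colour = "group") +
    ggplot2::theme_minimal()
}
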