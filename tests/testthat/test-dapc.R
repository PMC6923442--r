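test_that("dosage encoding counts alleles and recovers frequencies", {
  ds <- ds_from_strings(rbind(c("1/2"), c("1/1"), c("2/2")),
                        populations = rep("A", 3))
  m <- encode_alleles(ds)
  expect_equal(unname(m[1, ]), c(1, 1))
  expect_equal(unname(m[2, ]), c(2, 0))
  af <- allele_frequencies(ds, "A", "L1")
  expect_equal(unname(colSums(m) / (2 * 3)), unname(af$freq))
})

test_that("missing dosages are mean-imputed preserving column means", {
  ds <- ds_from_strings(rbind("1/2", "1/1", NA), populations = rep("A", 3))
  m <- encode_alleles(ds)
  expect_equal(unname(m[3, 1]), mean(c(1, 2)))
  m_na <- encode_alleles(ds, impute = FALSE)
  expect_true(all(is.na(m_na[3, ])))
})

test_that("DAPC separates planted clusters with posterior ~1", {
  g <- make_admixed_dataset(synth_config(
    n_clusters = 3, pop_sizes = c(x = 20, y = 20, z = 20),
    n_loci = 15, drift = 0.5, admixture_alpha = 1e-3, purity = 50,
    seed = 21))
  m <- encode_alleles(g$dataset)
  grp <- g$dataset$metadata$population
  fit <- dapc_fit(m, grp, n_pcs = 10)
  expect_equal(ncol(fit$specimen_coords), 2)    # groups - 1
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  self <- vapply(seq_len(nrow(m)), function(i)
    fit$posterior[i, grp[i]], numeric(1))
  expect_gt(mean(self), 0.99)
})

test_that("identical group distributions give posteriors near 1/2", {
  set.seed(9)
  g <- make_admixed_dataset(synth_config(
    n_clusters = 1, pop_sizes = c(a = 60), n_loci = 10, seed = 9))
  m <- encode_alleles(g$dataset)
  grp <- rep(c("u", "v"), 30)
  fit <- dapc_fit(m, grp, n_pcs = 5)
  self <- vapply(seq_len(nrow(m)), function(i)
    fit$posterior[i, grp[i]], numeric(1))
  expect_lt(mean(self), 0.75)
})

test_that("coordinates are invariant to column order up to axis sign", {
  g <- make_admixed_dataset(synth_config(seed = 13))
  m <- encode_alleles(g$dataset)
  grp <- g$dataset$metadata$population
  f1 <- dapc_fit(m, grp, 5)
  perm <- sample(ncol(m))
  f2 <- dapc_fit(m[, perm], grp, 5)
  for (ax in seq_len(ncol(f1$specimen_coords))) {
    d_same <- max(abs(f1$specimen_coords[, ax] - f2$specimen_coords[, ax]))
    d_flip <- max(abs(f1$specimen_coords[, ax] + f2$specimen_coords[, ax]))
    expect_lt(min(d_same, d_flip), 1e-6)
  }
})

test_that("cross-validation picks a PC count in the candidate set", {
  g <- make_admixed_dataset(synth_config(
    n_clusters = 2, pop_sizes = c(x = 20, y = 20), n_loci = 12,
    drift = 0.5, admixture_alpha = 1e-3, purity = 50, seed = 31))
  m <- encode_alleles(g$dataset)
  grp <- g$dataset$metadata$population
  xv <- xval_n_pcs(m, grp, folds = 4, candidate_pcs = c(2, 5, 8), seed = 2)
  expect_true(xv$n_pcs %in% c(2, 5, 8))
  expect_gt(max(xv$success, na.rm = TRUE), 0.9)

  # no-signal case: success near chance
  grp0 <- rep(c("u", "v"), 20)
  xv0 <- xval_n_pcs(m, grp0, folds = 4, candidate_pcs = c(2, 5), seed = 3)
  expect_lt(max(xv0$success, na.rm = TRUE), 0.8)
})

test_that("small groups reduce the fold count with a warning", {
  g <- make_admixed_dataset(synth_config(
    n_clusters = 2, pop_sizes = c(x = 3, y = 12), seed = 17))
  m <- encode_alleles(g$dataset)
  expect_warning(
    xval_n_pcs(m, g$dataset$metadata$population, folds = 5,
               candidate_pcs = c(2, 4), seed = 1),
    "smaller than fold count")
})
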