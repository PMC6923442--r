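test_that("admixed generator is seed-deterministic with a truth record", {
  cf <- synth_config(n_clusters = 2, pop_sizes = c(a = 8, b = 8),
                     n_loci = 5, seed = 42)
  g1 <- make_admixed_dataset(cf)
  g2 <- make_admixed_dataset(cf)
  expect_identical(g1$dataset$a1, g2$dataset$a1)
  expect_identical(g1$truth$q, g2$truth$q)
  expect_equal(dim(g1$truth$q), c(16, 2))
  expect_true(all(abs(rowSums(g1$truth$q) - 1) < 1e-12))
})

test_that("inbreeding = 1 yields only homozygous observed calls", {
  cf <- synth_config(n_clusters = 2, pop_sizes = c(a = 10, b = 10),
                     inbreeding = 1, seed = 3)
  g <- make_admixed_dataset(cf)
  obs <- !is.na(g$dataset$a1)
  expect_true(all(g$dataset$a1[obs] == g$dataset$a2[obs]))
})

test_that("tiny admixture alpha with high purity gives near-pure members", {
  cf <- synth_config(n_clusters = 3, admixture_alpha = 1e-4, purity = 50,
                     seed = 5)
  g <- make_admixed_dataset(cf)
  own <- vapply(seq_len(nrow(g$truth$q)), function(i)
    g$truth$q[i, g$truth$base_cluster[i]], numeric(1))
  expect_gt(mean(own), 0.99)
})

test_that("realized F_IS tracks the configured inbreeding coefficient", {
  cf <- synth_config(n_clusters = 1, pop_sizes = c(a = 400), n_loci = 20,
                     n_alleles = 4, inbreeding = 0.3, purity = 50,
                     drift = 0.2, seed = 11)
  g <- make_admixed_dataset(cf)
  s <- summarize_population(g$dataset, "a", n_permutations = 0)
  expect_lt(abs(s$fis - 0.3), 0.03)
})

test_that("generated datasets pass QC cleanly at default configs", {
  g <- make_admixed_dataset(synth_config(seed = 8))
  expect_no_warning(filter_missing_specimens(g$dataset))
  expect_no_warning(drop_monomorphic_loci(g$dataset))
})

test_that("paper-like preset reproduces the planted QC counts exactly", {
  pl <- make_paperlike_dataset(seed = 7)
  expect_equal(n_specimens(pl$dataset), 223)
  expect_equal(n_loci(pl$dataset), 15)
  qc <- qc_dataset(pl$dataset)
  expect_equal(qc$report$n_specimens_retained, 192)
  expect_length(qc$report$removed_specimens, 31)
  expect_equal(qc$report$n_loci_retained, 13)
  expect_equal(qc$report$removed_loci, c("SSR14", "SSR15"))
})

test_that("paper-like planted structure is seed-invariant for retained data", {
  d1 <- qc_dataset(make_paperlike_dataset(seed = 1)$dataset)$dataset
  d2 <- qc_dataset(make_paperlike_dataset(seed = 99)$dataset)$dataset
  expect_identical(d1$a1, d2$a1)
  s1 <- summarize_population(d1, "Berikon", n_permutations = 0)
  expect_equal(s1$na_mean, 27 / 13)
  expect_equal(s1$private_alleles, 1)
})

test_that("marly_demes relabels spots and drops unspotted specimens", {
  pl <- make_paperlike_dataset(seed = 2)
  d <- qc_dataset(pl$dataset)$dataset
  md <- marly_demes(d)
  tab <- table(md$metadata$population)
  expect_equal(as.integer(tab[c("Ma1", "Ma2", "Br")]), c(34L, 14L, 53L))
})
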