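test_that("theta equals 1 for fixed differences and ~0 for a random split", {
  m <- cbind(rep(c("1/1", "2/2"), each = 6),
             rep(c("5/5", "7/7"), each = 6))
  ds <- ds_from_strings(m, populations = rep(c("A", "B"), each = 6))
  r <- pairwise_fst(ds, "A", "B", n_permutations = 99, seed = 1)
  expect_equal(r$theta, 1)
  expect_lt(r$p_value, 0.05)

  # one panmictic population split arbitrarily in two
  ds0 <- random_dataset(n_pops = 1, n_per_pop = 40, n_loci = 6, seed = 2)
  ds0$metadata$population <- rep(c("X", "Y"), 20)
  r0 <- pairwise_fst(ds0, "X", "Y", n_permutations = 199, seed = 3)
  expect_lt(abs(r0$theta), 0.05)
  expect_gt(r0$p_value, 0.05)
})

test_that("multilocus theta matches the brute-force ANOVA oracle", {
  for (s in 1:20) {
    ds <- random_dataset(n_pops = sample(2:4, 1), n_per_pop = sample(4:9, 1),
                         n_loci = 3, n_alleles = sample(2:4, 1),
                         fst = runif(1, 0.05, 0.5), seed = 100 + s)
    # sprinkle missing calls
    set.seed(s)
    k <- sample(length(ds$a1), 3)
    ds$a1[k] <- NA; ds$a2[k] <- NA
    pops <- population_partition(ds)$names[1:2]
    got <- pairwise_fst(ds, pops[1], pops[2], n_permutations = 0)$theta
    expect_equal(got, oracle_wc_theta(ds, pops), tolerance = 1e-10)
  }
})

test_that("undefined theta is reported as an explicit status", {
  m <- matrix("4/4", 6, 2)
  ds <- ds_from_strings(m, populations = rep(c("A", "B"), each = 3))
  r <- pairwise_fst(ds, "A", "B", n_permutations = 9)
  expect_true(is.na(r$theta))
  expect_equal(r$status, "undefined")
  expect_error(pairwise_fst(ds, "A", "missing"), "unknown population")
})

test_that("fst_matrix covers all pairs and is seed-reproducible", {
  ds <- random_dataset(n_pops = 3, n_per_pop = 8, seed = 9)
  m1 <- fst_matrix(ds, n_permutations = 49, seed = 5)
  m2 <- fst_matrix(ds, n_permutations = 49, seed = 5)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 3)
  expect_true(all(m1$theta >= -1 & m1$theta <= 1))
  expect_true(all(m1$p_value > 0 & m1$p_value <= 1))
})
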