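test_that("biallelic HWE enumeration is an exact conditional test", {
  # known reference point: Louis & Dempster-style small table
  # genotypes: 3 AA, 4 AB, 3 BB (n = 10, nA = 10)
  m <- matrix(c(rep("1/1", 3), rep("1/2", 4), rep("2/2", 3)), ncol = 1)
  ds <- ds_from_strings(m, populations = rep("P", 10))
  r <- hwe_exact_test(ds, "P", "L1")
  expect_equal(r$method, "enumeration")
  # oracle: enumerate heterozygote counts directly
  hs <- seq(0, 10, by = 2)
  logw <- vapply(hs, function(h)
    h * log(2) - lgamma((10 - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((10 - h) / 2 + 1), numeric(1))
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  p_exact <- sum(pr[pr <= pr[hs == 4] * (1 + 1e-9)])
  expect_equal(r$p_value, p_exact)
})

test_that("Monte-Carlo HWE agrees with enumeration on biallelic tables", {
  m <- matrix(c(rep("1/1", 8), rep("1/2", 4), rep("2/2", 8)), ncol = 1)
  ds <- ds_from_strings(m, populations = rep("P", 20))
  exact <- hwe_exact_test(ds, "P", "L1")$p_value
  # force the Monte-Carlo path through the internal shuffle sampler
  x <- c(ds$a1[, 1], ds$a2[, 1])
  copies <- as.vector(rbind(ds$a1[, 1], ds$a2[, 1])) - 1L
  set.seed(42)
  res <- outbreakgen:::.hwe_shuffle_mc_cpp(as.integer(copies), 2L, 20000L)
  p_mc <- (res$n_le + 1) / 20001
  expect_lt(abs(p_mc - exact), 3 * sqrt(exact * (1 - exact) / 20000))
})

test_that("all-homozygote balanced sample is an extreme HWE violation", {
  m <- matrix(rep(c("1/1", "2/2"), 15), ncol = 1)
  ds <- ds_from_strings(m, populations = rep("P", 30))
  r <- hwe_exact_test(ds, "P", "L1")
  expect_lt(r$p_value, 0.001)
})

test_that("HWE test is reproducible under a seed and flags monomorphic loci", {
  ds <- random_dataset(n_pops = 1, n_per_pop = 25, n_loci = 1,
                       n_alleles = 5, seed = 8)
  r1 <- hwe_exact_test(ds, "pop1", "L1",
                       chain_config = list(n_samples = 2000), seed = 10)
  r2 <- hwe_exact_test(ds, "pop1", "L1",
                       chain_config = list(n_samples = 2000), seed = 10)
  expect_identical(r1, r2)
  expect_equal(r1$method, "monte-carlo")
  expect_gt(r1$se, 0)

  mono <- ds_from_strings(matrix("3/3", 5), populations = rep("P", 5))
  expect_equal(hwe_exact_test(mono, "P", "L1")$status, "not testable")
})

test_that("LD G statistic matches hand computation on a 2x2 table", {
  # locus A genotypes split 6/4, locus B 5/5, associated
  gA <- c(rep("1/1", 6), rep("1/2", 4))
  gB <- c(rep("3/3", 5), rep("3/4", 5))
  ds <- ds_from_strings(cbind(gA, gB), populations = rep("P", 10))
  r <- ld_test(ds, "P", c("L1", "L2"), n_permutations = 99, seed = 1)
  O <- table(gA, gB)
  E <- outer(rowSums(O), colSums(O)) / 10
  G_hand <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  expect_equal(r$g, G_hand)
})

test_that("a locus paired with itself hits the permutation floor", {
  set.seed(3)
  g <- sample(c("1/1", "1/2", "2/2", "2/3"), 40, TRUE)
  ds <- ds_from_strings(cbind(g, g), populations = rep("P", 40))
  r <- ld_test(ds, "P", c("L1", "L2"), n_permutations = 200, seed = 4)
  expect_equal(r$p_value, 1 / 201)
})

test_that("LD test is not testable within-population when a locus is fixed", {
  ds <- ds_from_strings(cbind(rep("1/1", 5), c("2/3", "2/2", "3/3", "2/3", "2/2")),
                        populations = rep("P", 5))
  expect_equal(ld_test(ds, "P", c("L1", "L2"))$status, "not testable")
})
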