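test_that("allele frequencies count genes correctly", {
  ds <- ds_from_strings(rbind("1/1", "1/2"), populations = c("A", "A"))
  af <- allele_frequencies(ds, "A", "L1")
  expect_equal(unname(af$freq), c(0.75, 0.25))
  expect_equal(af$n_genes, 4)
  # frequencies x 2n recover integer counts
  expect_equal(unname(af$freq * af$n_genes), c(3, 1))

  dsm <- ds_from_strings(rbind(NA, NA), populations = c("A", "A"))
  expect_error(allele_frequencies(dsm, "A", "L1"), "undefined")
})

test_that("population summary matches hand-computed Nei unbiased values", {
  # 2 specimens {A/A, A/B}: Hobs 0.5, Hexp (4/3)*0.375 = 0.5, Na 2
  ds <- ds_from_strings(rbind("1/1", "1/2"), populations = c("A", "A"))
  s <- summarize_population(ds, "A", n_permutations = 0)
  expect_equal(s$hobs_mean, 0.5)
  expect_equal(s$hexp_mean, 0.5)
  expect_equal(s$na_mean, 2)

  # monomorphic locus contributes Hexp = Hobs = 0, Na = 1
  ds2 <- ds_from_strings(rbind(c("1/1", "5/5"), c("1/2", "5/5")),
                         populations = c("A", "A"))
  s2 <- summarize_population(ds2, "A", n_permutations = 0)
  expect_equal(s2$na_mean, 1.5)
  expect_equal(s2$hexp_mean, 0.25)
  expect_equal(s2$hobs_mean, 0.25)
  # and can be excluded on request
  s2x <- summarize_population(ds2, "A", n_permutations = 0,
                              exclude_monomorphic = TRUE)
  expect_equal(s2x$na_mean, 2)

  # single-specimen population: unbiased factor 2, F_IS undefined
  ds1 <- ds_from_strings(rbind("1/2"), populations = "A")
  s1 <- summarize_population(ds1, "A", n_permutations = 0)
  expect_equal(s1$hexp_mean, 2 * (1 - 0.5))
  expect_true(is.na(s1$fis))
})

test_that("private alleles are counted against all other populations", {
  ds <- ds_from_strings(rbind(c("1/2"), c("1/3"), c("1/1"), c("2/2")),
                        populations = c("A", "A", "B", "B"))
  sA <- summarize_population(ds, "A", n_permutations = 0)
  sB <- summarize_population(ds, "B", n_permutations = 0)
  expect_equal(sA$private_alleles, 1)   # allele 3
  expect_equal(sB$private_alleles, 0)
})

test_that("E5 evenness is 1 for equal MLG frequencies, <1 for skew, NA for one", {
  even <- ds_from_strings(rbind("1/1", "2/2", "3/3"),
                          populations = rep("A", 3))
  expect_equal(mlg_evenness(even, "A"), 1)
  skew <- ds_from_strings(rbind("1/1", "1/1", "1/1", "1/1", "2/2"),
                          populations = rep("A", 5))
  expect_lt(mlg_evenness(skew, "A"), 1)
  mono <- ds_from_strings(rbind("1/1", "1/1"), populations = rep("A", 2))
  expect_true(is.na(mlg_evenness(mono, "A")))
})

test_that("unbiased Hexp always at least the plug-in gene diversity", {
  for (s in 1:10) {
    ds <- random_dataset(n_pops = 1, n_per_pop = 6, n_loci = 3, seed = s)
    su <- summarize_population(ds, "pop1", n_permutations = 0)
    plug <- mean(vapply(ds$loci, function(l) {
      af <- allele_frequencies(ds, "pop1", l)
      1 - sum(af$freq^2)
    }, numeric(1)))
    expect_gte(su$hexp_mean, plug - 1e-12)
  }
})

test_that("F_IS permutation flags strong heterozygote deficit", {
  # all homozygotes at an evenly split biallelic locus
  m <- matrix(rep(c("1/1", "2/2"), 10), ncol = 1)
  ds <- ds_from_strings(m, populations = rep("A", 20))
  s <- summarize_population(ds, "A", n_permutations = 199, seed = 7)
  expect_gt(s$fis, 0.9)
  expect_lt(s$fis_p, 0.02)
})

test_that("Holm sequential Bonferroni matches hand computation", {
  expect_equal(sequential_bonferroni(c(0.001, 0.02, 0.2)),
               c(TRUE, TRUE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_equal(sequential_bonferroni(0.04), TRUE)   # m = 1: plain alpha
  expect_equal(sequential_bonferroni(numeric(0)), logical(0))
  # monotone: flagged p_i implies all smaller p flagged
  set.seed(1)
  p <- runif(20)^2
  fl <- sequential_bonferroni(p)
  if (any(fl)) expect_true(all(fl[p < max(p[fl])]))
})
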