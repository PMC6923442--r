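test_that("constructor normalizes allele order and enforces invariants", {
  ds <- genotype_dataset(a1 = matrix(c(5L, 3L), 1), a2 = matrix(c(2L, 3L), 1),
                         specimen_ids = "x1", loci = c("La", "Lb"))
  expect_equal(unname(ds$a1[1, ]), c(2L, 3L))
  expect_equal(unname(ds$a2[1, ]), c(5L, 3L))

  expect_error(
    genotype_dataset(matrix(1L, 2, 1), matrix(1L, 2, 1),
                     c("a", "a"), "L1"),
    "duplicate specimen")
  expect_error(
    genotype_dataset(matrix(c(1L, NA), 1), matrix(c(2L, 3L), 1),
                     "a", c("L1", "L2")),
    "half-missing")
})

test_that("population partition follows metadata and preserves order", {
  ds <- ds_from_strings(rbind(c("1/1"), c("1/2"), c("2/2")),
                        populations = c("B", "A", NA))
  part <- population_partition(ds)
  expect_equal(part$names, c("B", "A"))
  expect_equal(part$members$A, "s2")
  expect_equal(sort(unname(unlist(part$members))), c("s1", "s2"))
  expect_error(population_members(ds, "Z"), "unknown population")
})

test_that("subsetting preserves order and metadata", {
  ds <- random_dataset(n_pops = 2, n_per_pop = 5, seed = 3)
  sub <- subset_dataset(ds, specimens = c("s004", "s002"), loci = c("L2"))
  expect_equal(sub$specimen_ids, c("s004", "s002"))
  expect_equal(sub$loci, "L2")
  expect_equal(sub$metadata$population, ds$metadata$population[c(4, 2)])
})
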