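test_that("missingness filter removes strictly-above-threshold specimens", {
  # 15 loci; specimen 2 misses 2/15 = 13.3% -> removed at 0.10
  m <- matrix("1/2", 3, 15)
  m[2, 1:2] <- NA
  m[3, 1] <- NA                     # 6.7%: kept
  ds <- ds_from_strings(m)
  out <- filter_missing_specimens(ds, 0.10)
  expect_equal(attr(out, "removed"), "s2")
  expect_equal(n_specimens(out), 2)

  # threshold 1.0 removes nothing
  out2 <- filter_missing_specimens(ds, 1.0)
  expect_equal(n_specimens(out2), 3)

  # idempotent
  out3 <- filter_missing_specimens(out, 0.10)
  expect_equal(out3$specimen_ids, out$specimen_ids)

  # all removed warns rather than crashes
  mall <- matrix(NA_character_, 2, 15)
  expect_warning(filter_missing_specimens(ds_from_strings(mall), 0.10),
                 "all specimens removed")
})

test_that("monomorphic loci are dropped, polymorphic kept, idempotently", {
  m <- rbind(c("7/7", "7/8", "7/7"),
             c("7/7", "7/7", NA),
             c(NA,    "8/8", "7/7"))
  ds <- ds_from_strings(m)
  out <- drop_monomorphic_loci(ds)
  expect_equal(attr(out, "removed"), c("L1", "L3"))
  expect_equal(out$loci, "L2")
  out2 <- drop_monomorphic_loci(out)
  expect_equal(out2$loci, out$loci)
  expect_length(attr(out2, "removed"), 0)
})

test_that("unique MLG counting is bounded and handles missing patterns", {
  m <- rbind(c("1/2", "3/3"), c("1/2", "3/3"), c("1/2", "3/3"))
  ds <- ds_from_strings(m, populations = rep("A", 3))
  expect_equal(count_unique_mlg(ds, "A"), 1)

  m2 <- rbind(c("1/2", "3/3"), c("1/1", "3/3"), c("1/2", "3/4"))
  ds2 <- ds_from_strings(m2, populations = rep("A", 3))
  expect_equal(count_unique_mlg(ds2, "A"), 3)

  # conservative rule: identical observed loci but different missing
  # pattern -> distinct; relaxed rule merges them
  m3 <- rbind(c("1/2", "3/3"), c("1/2", NA))
  ds3 <- ds_from_strings(m3, populations = rep("A", 2))
  expect_equal(count_unique_mlg(ds3, "A"), 2)
  expect_equal(count_unique_mlg(ds3, "A", missing_matches_any = TRUE), 1)

  expect_error(count_unique_mlg(ds3, "nope"), "unknown population")

  # bounds on random data
  ds4 <- random_dataset(n_pops = 1, n_per_pop = 8, seed = 5)
  u <- count_unique_mlg(ds4, "pop1")
  expect_gte(u, 1); expect_lte(u, 8)
})

test_that("qc_dataset combines both filters and reports counts", {
  m <- matrix("1/2", 4, 15)
  m[, 15] <- "9/9"                  # monomorphic locus
  m[1, 1:3] <- NA                   # 20% missing -> removed
  ds <- ds_from_strings(m)
  qc <- qc_dataset(ds)
  expect_equal(qc$report$n_specimens_retained, 3)
  expect_equal(qc$report$n_loci_retained, 14)
  expect_equal(qc$report$removed_specimens, "s1")
  expect_equal(qc$report$removed_loci, "L15")
})
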