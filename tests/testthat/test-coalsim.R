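test_that("zero mutation rate yields monomorphic loci", {
  ds <- simulate_dataset(default_scenarios()$SC5, sc5_params(),
                         c(Ma1 = 10, Ma2 = 10, Br = 10), n_loci = 5,
                         mutation = mutation_model(mu_mean = 0, gsm_p = 0),
                         seed = 2)
  for (l in 1:5)
    expect_length(unique(c(ds$a1[, l], ds$a2[, l])), 1)
})

test_that("simulations are seed-deterministic", {
  d1 <- simulate_dataset(default_scenarios()$SC5, sc5_params(),
                         c(Ma1 = 10, Ma2 = 5, Br = 10), n_loci = 4, seed = 5)
  d2 <- simulate_dataset(default_scenarios()$SC5, sc5_params(),
                         c(Ma1 = 10, Ma2 = 5, Br = 10), n_loci = 4, seed = 5)
  expect_identical(d1$a1, d2$a1)
})

test_that("strict-SMM equilibrium heterozygosity matches the closed form", {
  # single constant-size deme: E[H] = 1 - 1/sqrt(1 + 8 N mu)
  for (case in list(c(N = 500, mu = 1e-3), c(N = 50, mu = 1e-3))) {
    N <- case["N"]; mu <- case["mu"]
    ds <- simulate_dataset(one_deme_scenario(), list(N = N),
                           c(SRC = 25), n_loci = 600,
                           mutation = mutation_model(mu_mean = mu,
                                                     gsm_p = 0,
                                                     rate_shape = Inf),
                           seed = 31)
    H <- vapply(seq_len(600), function(l) {
      x <- c(ds$a1[, l], ds$a2[, l])
      (length(x) / (length(x) - 1)) * (1 - sum((table(x) / length(x))^2))
    }, numeric(1))
    expected <- 1 - 1 / sqrt(1 + 8 * N * mu)
    se <- sd(H) / sqrt(length(H))
    expect_lt(abs(mean(H) - expected), 3 * se + 1e-6)
  }
})

test_that("F_ST grows with divergence time between two demes", {
  sc <- parse_scenario(paste(
    "scenario SPLIT",
    "deme A size 200",
    "deme SRC size 200 ancestral",
    "event found A from SRC at tsplit founder 200 duration 0",
    sep = "\n"))
  fst_at <- function(t) {
    mean(vapply(1:8, function(r) {
      ds <- simulate_dataset(sc, list(tsplit = t), c(A = 20, SRC = 20),
                             n_loci = 12,
                             mutation = mutation_model(mu_mean = 1e-3,
                                                       gsm_p = 0),
                             seed = 400 + 17 * r + round(t))
      pairwise_fst(ds, "A", "SRC", n_permutations = 0)$theta
    }, numeric(1)))
  }
  f <- vapply(c(5, 50, 300), fst_at, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("summary statistics are exchangeable under specimen relabelling", {
  ds <- simulate_dataset(default_scenarios()$SC5, sc5_params(),
                         c(Ma1 = 12, Ma2 = 8, Br = 12), n_loci = 6,
                         seed = 8)
  st1 <- compute_sumstats(ds)
  set.seed(2)
  # permute specimens within each deme
  ord <- unlist(lapply(unique(ds$metadata$population), function(p)
    sample(which(ds$metadata$population == p))))
  ds2 <- subset_dataset(ds, specimens = ord)
  st2 <- compute_sumstats(ds2)
  expect_equal(st1, st2)
})

test_that("sumstats match the reference R implementation", {
  for (s in 1:5) {
    ds <- simulate_dataset(default_scenarios()$SC1, sc5_params(),
                           c(Ma1 = 9, Ma2 = 7, Br = 11), n_loci = 5,
                           seed = 50 + s)
    idx <- lapply(c("Ma1", "Ma2", "Br"), function(d)
      which(ds$metadata$population == d))
    expect_equal(
      outbreakgen:::.sumstats_idx(ds$a1, ds$a2, idx, c("Ma1", "Ma2", "Br")),
      outbreakgen:::.sumstats_idx_r(ds$a1, ds$a2, idx, c("Ma1", "Ma2", "Br")),
      tolerance = 1e-10)
  }
})

test_that("sumstat vector has the documented schema", {
  ds <- simulate_dataset(default_scenarios()$SC5, sc5_params(),
                         c(Ma1 = 6, Ma2 = 6, Br = 6), n_loci = 3, seed = 3)
  st <- compute_sumstats(ds)
  expect_length(st, 4 * 3 + 3 * 3)
  expect_true(all(c("na.Ma1", "gw.Br", "fst.Ma1_Ma2", "dmu2.Ma2_Br")
                  %in% names(st)))
  # identical demes: fst ~ 0, das = 0
  dd <- ds
  dd$a1[dd$metadata$population == "Ma2", ] <-
    dd$a1[dd$metadata$population == "Ma1", ]
  dd$a2[dd$metadata$population == "Ma2", ] <-
    dd$a2[dd$metadata$population == "Ma1", ]
  st2 <- compute_sumstats(dd)
  expect_equal(unname(st2["das.Ma1_Ma2"]), 0)
  expect_lt(st2["fst.Ma1_Ma2"], 0.02)
})

test_that("(delta mu)^2 equals the squared difference of mean sizes", {
  # one locus; deme A mean repeat 10, deme B mean 13
  ds <- ds_from_strings(rbind("10/10", "10/10", "13/13", "13/13"),
                        populations = c("A", "A", "B", "B"))
  st <- compute_sumstats(ds)
  expect_equal(unname(st["dmu2.A_B"]), 9)
})

test_that("zero sample sizes are rejected", {
  expect_error(simulate_dataset(default_scenarios()$SC5, sc5_params(),
                                c(Ma1 = 0, Ma2 = 5, Br = 5)),
               "positive")
})
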