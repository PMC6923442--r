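# small hand-built reference table: two scenarios with controllable
# separation in a 4-statistic space
toy_table <- function(n = 400, sep = 5, seed = 1) {
  set.seed(seed)
  stats <- rbind(matrix(rnorm(n * 4), n, 4),
                 matrix(rnorm(n * 4, mean = sep), n, 4))
  colnames(stats) <- paste0("s", 1:4)
  pr <- prior_spec(list(N = list(dist = "unif", min = 10, max = 100)))
  structure(list(
    scenario = factor(rep(c("A", "B"), each = n), levels = c("A", "B")),
    params = data.frame(N = runif(2 * n, 10, 100)),
    stats = stats, priors = pr), class = "reference_table")
}

test_that("reference table is balanced and seed-deterministic", {
  scs <- default_scenarios()[c("SC5", "SC6")]
  pr <- default_priors(step2 = TRUE)
  cfg <- c(Ma1 = 8, Ma2 = 6, Br = 8)
  t1 <- build_reference_table(scs, pr, 30, cfg, n_loci = 5, seed = 3)
  t2 <- build_reference_table(scs, pr, 30, cfg, n_loci = 5, seed = 3)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)
  expect_equal(as.integer(table(t1$scenario)), c(30, 30))
  expect_true(all(is.finite(t1$stats)))
})

test_that("direct selection assigns an in-scenario observation correctly", {
  tab <- toy_table(sep = 6)
  obs <- tab$stats[3, ]                 # a scenario-A row
  sel <- select_scenario_direct(obs, tab, n_closest = 100)
  expect_equal(sel$best, "A")
  expect_gt(sel$posterior$probability[sel$posterior$scenario == "A"], 0.5)
  expect_equal(sum(sel$posterior$probability), 1)
  expect_true(all(sel$posterior$ci_lo <= sel$posterior$probability &
                  sel$posterior$probability <= sel$posterior$ci_hi))

  # indistinguishable scenarios: probabilities near the prior shares
  tab0 <- toy_table(sep = 0)
  sel0 <- select_scenario_direct(rnorm(4), tab0, n_closest = 200)
  expect_lt(max(abs(sel0$posterior$probability - 0.5)), 0.2)
})

test_that("zero-variance statistics are dropped with a warning", {
  tab <- toy_table()
  tab$stats[, 2] <- 7
  obs <- c(tab$stats[1, 1], 7, tab$stats[1, 3:4])
  expect_warning(sel <- select_scenario_direct(obs, tab, 50),
                 "zero-variance")
  expect_equal(sum(sel$posterior$probability), 1)
})

test_that("LDA + logistic selection works and sums to one", {
  tab <- toy_table(sep = 3)
  obs <- tab$stats[5, ]
  sel <- select_scenario_lda_logistic(obs, tab, fraction = 0.6)
  expect_equal(sel$best, "A")
  expect_equal(sum(sel$posterior$probability), 1, tolerance = 1e-9)
  expect_gt(sel$posterior$probability[1], 0.5)
  expect_true(all(diff(c(sel$posterior$ci_lo[1],
                         sel$posterior$probability[1],
                         sel$posterior$ci_hi[1])) >= 0))

  one <- toy_table()
  one$scenario <- factor(rep("A", nrow(one$stats)), levels = "A")
  expect_error(select_scenario_lda_logistic(one$stats[1, ], one),
               ">= 2 scenarios")
})

test_that("selection methods agree on well-separated toys", {
  tab <- toy_table(sep = 6, seed = 5)
  agree <- vapply(1:20, function(i) {
    obs <- tab$stats[i, ] + rnorm(4, sd = 0.3)
    d <- select_scenario_direct(obs, tab, 100)$best
    l <- suppressWarnings(
      select_scenario_lda_logistic(obs, tab, fraction = 0.2)$best)
    d == l
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("parameter estimation stays inside prior bounds and adjusts", {
  set.seed(11)
  n <- 3000
  N <- runif(n, 10, 100)
  stats <- cbind(s1 = N / 50 + rnorm(n, sd = 0.08),
                 s2 = rnorm(n))
  pr <- prior_spec(list(N = list(dist = "unif", min = 10, max = 100)))
  tab <- structure(list(scenario = factor(rep("A", n)),
                        params = data.frame(N = N),
                        stats = stats, priors = pr),
                   class = "reference_table")
  true_N <- 62
  obs <- c(s1 = true_N / 50, s2 = 0)
  est <- estimate_parameters(obs, tab, fraction = 0.05)
  expect_true(all(est$adjusted[, "N"] >= 10 & est$adjusted[, "N"] <= 100))
  expect_lt(abs(est$summary$mode - true_N), 10)
  expect_true(est$summary$q025 <= est$summary$median &
              est$summary$median <= est$summary$q975)
  expect_error(estimate_parameters(obs, tab, fraction = 0.001,
                                   min_rows = 0),
               "< 50")
})

test_that("scenario confidence errors reflect separation", {
  tab <- toy_table(n = 300, sep = 6, seed = 7)
  conf <- scenario_confidence(tab, "A", n_pods = 40, seed = 2,
                              n_closest = 100)
  expect_lt(conf$type1, 0.05)
  expect_lt(conf$type2, 0.05)

  tab0 <- toy_table(n = 300, sep = 0, seed = 8)
  conf0 <- scenario_confidence(tab0, "A", n_pods = 40, seed = 3,
                               n_closest = 100)
  expect_lt(abs(conf0$type1 - 0.5), 0.25)   # chance level for 2 scenarios
  expect_error(scenario_confidence(tab0, "A", n_pods = 1000),
               "exceeds")
})

test_that("goodness-of-fit tail areas behave at both extremes", {
  set.seed(13)
  sims <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(NULL, paste0("s", 1:5)))
  # observed drawn from the predictive: tails comfortably off the floor
  gof1 <- goodness_of_fit(setNames(rnorm(5), paste0("s", 1:5)), sims)
  expect_true(all(gof1$tails$p_tail > 2 / 201))
  # far-outlying observation hits the add-one floor
  gof2 <- goodness_of_fit(setNames(rep(50, 5), paste0("s", 1:5)), sims)
  expect_true(all(gof2$tails$p_tail <= 2 / 201 + 1e-12))
  # every statistic is covered
  expect_equal(gof1$tails$statistic, paste0("s", 1:5))
  # tail probabilities roughly uniform over repeated in-model draws
  ps <- vapply(1:200, function(i)
    goodness_of_fit(setNames(rnorm(5), paste0("s", 1:5)),
                    sims)$tails$p_tail[1], numeric(1))
  expect_gt(mean(ps > 0.5), 0.3)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("outbreak generator wraps the simulator with truth and trees", {
  g <- make_outbreak_dataset(default_scenarios()$SC5,
                             sc5_params(), c(Ma1 = 8, Ma2 = 6, Br = 8),
                             n_loci = 4, seed = 21, trees_per_deme = 3)
  expect_s3_class(g$dataset, "genotype_dataset")
  expect_equal(g$truth$scenario$name, "SC5")
  expect_equal(length(unique(na.omit(g$dataset$metadata$tree))), 9)
  g2 <- make_outbreak_dataset(default_scenarios()$SC5,
                              sc5_params(), c(Ma1 = 8, Ma2 = 6, Br = 8),
                              n_loci = 4, seed = 21, trees_per_deme = 3)
  expect_identical(g$dataset$a1, g2$dataset$a1)
})
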