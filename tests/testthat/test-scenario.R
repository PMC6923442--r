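test_that("scenario text round-trips through parse and format", {
  for (sc in default_scenarios()) {
    back <- parse_scenario(format_scenario(sc))
    expect_equal(back, sc)
  }
  sc5 <- default_scenarios()$SC5
  expect_equal(sc5$ancestral, "SRC")
  expect_equal(nrow(sc5$events), 3)
  expect_setequal(sc5$demes, c("Ma1", "Ma2", "Br", "SRC"))
})

test_that("ill-formed scenarios are rejected with the offending element", {
  expect_error(parse_scenario(paste(
    "scenario bad",
    "deme A size N_A",
    "deme SRC size N_S ancestral",
    sep = "\n")), "never founded")
  expect_error(parse_scenario(paste(
    "scenario bad",
    "deme A size N_A",
    "deme B size N_B",
    "deme SRC size N_S ancestral",
    "event found A from B at t1 founder Nb duration db",
    "event found B from A at t2 founder Nb duration db",
    sep = "\n")), "cycle")
  expect_error(parse_scenario(paste(
    "scenario bad",
    "deme A size N_A",
    sep = "\n")), "ancestral")
  expect_error(parse_scenario(paste(
    "scenario bad",
    "deme A size N_A",
    "deme SRC size N_S ancestral",
    "event found A from SRC at t1 founder Nb",
    sep = "\n")), "bad event")
})

test_that("unbound scenario symbols fail at simulation time", {
  sc <- default_scenarios()$SC6
  expect_error(
    simulate_dataset(sc, list(N_Ma1 = 100), c(Ma1 = 5, Ma2 = 5, Br = 5)),
    "unbound symbol")
})

test_that("prior draws respect bounds, distributions and constraints", {
  pr <- default_priors()
  draws <- sample_prior(pr, 200, seed = 4)
  expect_true(all(draws$N_Ma1 >= 10 & draws$N_Ma1 <= 10000))
  expect_true(all(draws$t2 < draws$t1))
  expect_true(all(draws$t3 < draws$t1))
  expect_true(all(draws$db_Ma1 < draws$t1))

  # marginal shape: uniform parameter passes a KS test
  pr2 <- prior_spec(list(x = list(dist = "unif", min = 2, max = 7)))
  u <- sample_prior(pr2, 10000, seed = 9)$x
  ks <- suppressWarnings(stats::ks.test((u - 2) / 5, "punif"))
  expect_gt(ks$p.value, 0.001)
  # log-uniform: log is uniform
  pr3 <- prior_spec(list(x = list(dist = "logunif", min = 1, max = 1000)))
  v <- log(sample_prior(pr3, 10000, seed = 10)$x) / log(1000)
  ks2 <- suppressWarnings(stats::ks.test(v, "punif"))
  expect_gt(ks2$p.value, 0.001)

  expect_error(
    sample_prior(prior_spec(list(a = list(dist = "unif", min = 0, max = 1),
                                 b = list(dist = "unif", min = 2, max = 3)),
                            constraints = "b < a"), 1, seed = 1,
                 max_tries = 50),
    "unsatisfiable")
})
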