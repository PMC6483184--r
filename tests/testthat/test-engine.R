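test_that("a year with no rounds and no demographic events is a no-op", {
  cfg <- simulation_config("model1", "fixed", N0 = 20, b = 0, r = 0.1,
                           d = 0, rounds_per_year = 0, years = 1)
  set.seed(31)
  pop <- conservative_population(20)
  out <- run_year(pop, cfg)
  expect_identical(out$probs, pop$probs)
  expect_identical(out$year, pop$year + 1L)
})

test_that("without innovation the novel variant never appears", {
  cfg <- simulation_config("model1", "expanding", N0 = 50, mu = 0,
                           rounds_per_year = 30, years = 10)
  tr <- run_simulation(cfg, seed = 32)
  expect_identical(tr$mean_novel, rep(0, 11))
  cfg2 <- simulation_config("model2", "fixed", N0 = 50, mu = 0,
                            rounds_per_year = 30, years = 10)
  expect_identical(run_simulation(cfg2, seed = 33)$mean_novel, rep(0, 11))
})

test_that("an all-novel population is absorbing", {
  cfg <- simulation_config("model1", "fixed", N0 = 40, mu = 0,
                           rounds_per_year = 30, years = 8, d = 0.05)
  probs <- matrix(c(0, 1), 40, 2, byrow = TRUE)
  start <- new_population(probs, rep("L1", 40))
  tr <- run_simulation(cfg, seed = 34, initial_population = start)
  expect_identical(tr$mean_novel, rep(1, 9))
})

test_that("the fixed regime keeps N constant through a year", {
  cfg <- simulation_config("model1", "fixed", N0 = 100, mu = 0.05,
                           d = 0.05, rounds_per_year = 10, years = 1)
  set.seed(35)
  pop <- conservative_population(100)
  out <- run_year(pop, cfg)
  expect_identical(n_agents(out), 100L)
  expect_identical(sum(out$tenure == 0L), 5L)  # the five replacements
})

test_that("SLA innovation only touches L2 speakers inside the window", {
  prm <- learning_params(mu = 1)
  probs <- matrix(c(1, 0), 30, 2, byrow = TRUE)
  old <- new_population(probs, rep("L2", 30), tenure = rep(8L, 30))
  expect_identical(sla_mutation_pass(old, prm, 7L)$probs, probs)

  young <- new_population(probs, rep("L2", 30), tenure = rep(3L, 30))
  out <- sla_mutation_pass(young, prm, 7L)
  expect_true(all(out$probs[, 2] == 1))
  expect_identical(out$innovations, 30L)

  l1 <- new_population(probs, rep("L1", 30), tenure = rep(1L, 30))
  expect_identical(sla_mutation_pass(l1, prm, 7L)$probs, probs)
})

test_that("SLA innovation counts are binomial in the eligible pool", {
  set.seed(36)
  n <- 1e4
  probs <- matrix(c(1, 0), n, 2, byrow = TRUE)
  pop <- new_population(probs, rep("L2", n), tenure = rep(2L, n))
  out <- sla_mutation_pass(pop, learning_params(mu = 0.05), 7L)
  hits <- sum(out$probs[, 2] == 1)
  expect_lt(abs(hits - 500), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("the entry-counting switch sets the opportunity window", {
  prm <- learning_params(mu = 1)
  probs <- matrix(c(1, 0), 5, 2, byrow = TRUE)
  pop <- new_population(probs, rep("L2", 5), tenure = rep(7L, 5))
  # entry counts: tenure 7 is past the window
  expect_identical(sla_mutation_pass(pop, prm, 7L, entry_counts = TRUE)$probs,
                   probs)
  # annual passes on top of entry: tenure 7 still eligible
  out <- sla_mutation_pass(pop, prm, 7L, entry_counts = FALSE)
  expect_true(all(out$probs[, 2] == 1))
})

test_that("model 2 with a one-year window reduces to model 1", {
  census <- data.frame(year = c(0, 6), l1_count = c(20, 40),
                       l2_count = c(30, 90))
  base <- list(regime = "census", census = census, mu = 0.2,
               rounds_per_year = 20, scale = 1)
  cfg1 <- do.call(simulation_config, c(list(model = "model1"), base))
  cfg2 <- do.call(simulation_config, c(list(model = "model2",
                                            sla_window_years = 1), base))
  t1 <- run_simulation(cfg1, seed = 37)
  t2 <- run_simulation(cfg2, seed = 37)
  expect_identical(t1$mean_novel, t2$mean_novel)
  expect_identical(t1$innovations, t2$innovations)
})

test_that("ensembles are reproducible and summarize run spread", {
  cfg <- simulation_config("model1", "fixed", N0 = 30, mu = 0.1, d = 0.1,
                           rounds_per_year = 10, years = 5)
  e1 <- run_ensemble(cfg, n_runs = 4, master_seed = 38)
  e2 <- run_ensemble(cfg, n_runs = 4, master_seed = 38)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$runs, e2$runs)
  expect_true(all(e1$runs$mean_novel >= 0 & e1$runs$mean_novel <= 1))
  expect_equal(nrow(e1$summary), 6)
  y5 <- e1$runs$mean_novel[e1$runs$year == 5]
  expect_equal(e1$summary$mean[6], mean(y5))
  expect_equal(e1$summary$sd[6], sd(y5))
})

test_that("a single-run ensemble flags the undefined interval", {
  expect_warning(iv <- ensemble_interval(0.3), "single run")
  expect_true(is.na(iv[["sd"]]))
})

test_that("census-regime trajectories carry calendar years and sizes", {
  cfg <- simulation_config("model1", "census", census = maputo_census(),
                           mu = 0.05, scale = 1000, rounds_per_year = 5)
  tr <- run_simulation(cfg, seed = 39)
  expect_identical(tr$year, 1975:2007)
  expect_identical(tr$n[1], 20L)  # (100 + 20000) / 1000, rounded classes
  expect_identical(tr$n, tr$n_l1 + tr$n_l2)
})
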