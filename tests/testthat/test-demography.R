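prm0 <- learning_params(l = 0.05, mu = 0)

test_that("the fixed regime replaces exactly round(d*N) agents", {
  set.seed(21)
  pop <- conservative_population(100)
  pop$tenure <- rep(5L, 100)           # mark incumbents; entrants get 0
  out <- fixed_step(pop, rate_set(b = 0.007, r = 0.063, d = 0.05), prm0)
  expect_identical(n_agents(out), 100L)
  expect_identical(sum(out$tenure == 0L), 5L)

  # b = 0: every replacement is an L2 recruit
  pop <- conservative_population(60)
  out <- fixed_step(pop, rate_set(b = 0, r = 0.1, d = 0.1), prm0)
  expect_identical(sum(out$speaker_class == "L2"), 6L)
  expect_error(fixed_step(pop, rate_set(b = 0, r = 0, d = 0.1), prm0),
               "b \\+ r > 0")
})

test_that("replacements split births vs recruits as b/(b+r)", {
  set.seed(22)
  births <- 0L
  for (i in 1:100) {
    pop <- conservative_population(n_l1 = 0, n_l2 = 200)
    out <- fixed_step(pop, rate_set(b = 0.007, r = 0.063, d = 0.5), prm0)
    births <- births + sum(out$speaker_class == "L1")
  }
  n_repl <- 100 * 100  # 100 steps x round(0.5 * 200) replacements
  se <- sqrt(n_repl * 0.1 * 0.9)
  expect_lt(abs(births - 0.1 * n_repl), 3 * se)
})

test_that("the expanding regime grows at rate g = b + r - d", {
  pop <- conservative_population(40)
  out <- expanding_step(pop, rate_set(0, 0, 0), prm0)
  expect_identical(out$probs, pop$probs)

  set.seed(23)
  rates <- rate_set(b = 0.007, r = 0.063, d = 0.02)  # g = 0.05
  final_n <- vapply(1:6, function(i) {
    pop <- conservative_population(100)
    for (y in 1:40) pop <- expanding_step(pop, rates, prm0)
    n_agents(pop)
  }, integer(1))
  expected <- 100 * 1.05^40
  se <- sd(final_n) / sqrt(length(final_n))
  expect_lt(abs(mean(final_n) - expected), 3 * se)
})

test_that("stochastic remainder rounding is unbiased", {
  set.seed(24)
  x <- 3.7
  draws <- replicate(4000, shiftsim:::stoch_round(x))
  expect_true(all(draws %in% c(3L, 4L)))
  expect_lt(abs(mean(draws) - x), 3 * sqrt(0.7 * 0.3 / 4000))
})

test_that("a constant census with zero mortality gives an empty schedule", {
  census <- data.frame(year = c(2000, 2005), l1_count = c(50, 50),
                       l2_count = c(500, 500))
  sched <- census_to_schedule(census, mortality = 0)
  expect_true(all(sched$deaths == 0))
  expect_true(all(sched$births == 0))
  expect_true(all(sched$recruits == 0))
})

test_that("geometric interpolation gives sqrt(2)-growth recruit counts", {
  census <- data.frame(year = c(0, 2), l1_count = c(500, 500),
                       l2_count = c(10000, 20000))
  sched <- census_to_schedule(census, mortality = 0)
  expect_equal(sched$recruits, c(round(10000 * sqrt(2)) - 10000,
                                 20000 - round(10000 * sqrt(2))))
  expect_equal(sched$recruits[1], 4142)
})

test_that("the Maputo schedule reproduces Table counts exactly at scale 1", {
  census <- maputo_census()
  sched <- census_to_schedule(census, mortality = 0.02, scale = 1)
  l1 <- census$l1_count[1]; l2 <- census$l2_count[1]
  for (i in seq_len(nrow(sched))) {
    l1 <- l1 - sched$deaths_l1[i] + sched$births[i]
    l2 <- l2 - sched$deaths_l2[i] + sched$recruits[i]
    y <- sched$year[i] + 1
    j <- match(y, census$year)
    if (!is.na(j)) {
      expect_identical(l1, census$l1_count[j])
      expect_identical(l2, census$l2_count[j])
    }
  }
})

test_that("applying a schedule to agents hits the class targets", {
  set.seed(25)
  census <- data.frame(year = c(0, 3), l1_count = c(5, 10),
                       l2_count = c(5, 8))
  sched <- census_to_schedule(census, mortality = 0.1)
  targ <- attr(sched, "targets")
  pop <- conservative_population(n_l1 = 5, n_l2 = 5, year = 0)
  for (i in seq_len(nrow(sched))) {
    pop <- schedule_step(pop, sched, prm0)
    pop$year <- pop$year + 1L
    expect_identical(sum(pop$speaker_class == "L1"), as.integer(targ$l1[i + 1]))
    expect_identical(sum(pop$speaker_class == "L2"), as.integer(targ$l2[i + 1]))
  }
})

test_that("shrinkage beyond mortality clamps recruits and warns", {
  census <- data.frame(year = c(0, 2), l1_count = c(100, 100),
                       l2_count = c(1000, 100))
  expect_warning(sched <- census_to_schedule(census, mortality = 0),
                 "clamped")
  expect_true(all(sched$recruits == 0))
  l2 <- 1000 - sum(sched$deaths_l2) + sum(sched$recruits)
  expect_identical(l2, 100)
})

test_that("scaled schedules have proportionally scaled event counts", {
  census <- data.frame(year = c(0, 10), l1_count = c(2000, 8000),
                       l2_count = c(10000, 40000))
  full <- census_to_schedule(census, mortality = 0.02, scale = 1)
  set.seed(26)
  tot10 <- replicate(40, {
    s <- census_to_schedule(census, mortality = 0.02, scale = 10)
    sum(s$recruits)
  })
  expect_lt(abs(mean(tot10) - sum(full$recruits) / 10),
            0.05 * sum(full$recruits) / 10)
})

test_that("census tables are validated", {
  expect_error(census_to_schedule(data.frame(year = c(2, 1),
                                             l1_count = c(1, 1),
                                             l2_count = c(1, 1))),
               "strictly increasing")
  expect_error(census_to_schedule(data.frame(year = c(1, 2),
                                             l1_count = c(-1, 1),
                                             l2_count = c(1, 1))),
               "non-negative")
})
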