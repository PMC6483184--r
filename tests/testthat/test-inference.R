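test_that("the beta-binomial log-likelihood matches closed forms", {
  one <- data.frame(tokens = 1L, novel = 1L)
  expect_equal(betabinom_loglik(one, 1, 1), log(0.5))
  for (ab in list(c(2, 3), c(0.5, 0.5), c(10, 1))) {
    expect_equal(betabinom_loglik(one, ab[1], ab[2]),
                 log(ab[1] / (ab[1] + ab[2])))
  }
  zero <- data.frame(tokens = 1L, novel = 0L)
  expect_equal(betabinom_loglik(zero, 2, 3), log(3 / 5))
  expect_error(betabinom_loglik(one, -1, 2), "positive")
})

test_that("the log-likelihood agrees with the quadrature oracle", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:30, 5, replace = TRUE)
    x <- rbinom(5, n, runif(1))
    a <- runif(1, 0.3, 20); b <- runif(1, 0.3, 20)
    counts <- data.frame(tokens = n, novel = x)
    oracle <- sum(mapply(bb_log_density_quad, x, n,
                         MoreArgs = list(alpha = a, beta = b)))
    expect_lt(abs(betabinom_loglik(counts, a, b) - oracle), 1e-8)
  }
})

test_that("speaker counts are validated row-wise", {
  bad <- data.frame(tokens = c(10, 5), novel = c(3, 7))
  expect_error(validate_speaker_counts(bad), "row\\(s\\) 2")
  expect_error(validate_speaker_counts(data.frame(tokens = 0, novel = 0)),
               "row\\(s\\) 1")
})

test_that("boundary datasets get boundary fits instead of failures", {
  zeros <- data.frame(tokens = rep(10L, 5), novel = rep(0L, 5))
  fit <- fit_betabinom(zeros, bootstrap_reps = 0)
  expect_identical(fit$mean, 0)
  expect_true(fit$boundary)
  ones <- data.frame(tokens = rep(10L, 5), novel = rep(10L, 5))
  expect_identical(fit_betabinom(ones, bootstrap_reps = 0)$mean, 1)
})

test_that("mirror-symmetric counts fit a mean of one half", {
  counts <- data.frame(tokens = rep(20L, 8),
                       novel = c(8L, 12L, 9L, 11L, 10L, 10L, 7L, 13L))
  fit <- fit_betabinom(counts, bootstrap_reps = 0)
  expect_lt(abs(fit$mean - 0.5), 1e-4)
  expect_equal(fit$loglik, betabinom_loglik(counts, fit$alpha, fit$beta))
})

test_that("the fitted mean is consistent across the parameter grid", {
  set.seed(42)
  for (m in c(0.05, 0.2, 0.3)) {
    for (conc in c(2, 50)) {
      est <- vapply(1:60, function(i) {
        counts <- generate_speaker_counts(200, tokens = 20, mean = m,
                                          concentration = conc)
        fit_betabinom(counts, bootstrap_reps = 0)$mean
      }, numeric(1))
      expect_lt(abs(mean(est) - m), 0.01)
    }
  }
})

test_that("per-year fits return one MLE per recording year", {
  set.seed(43)
  counts <- rbind(
    generate_speaker_counts(40, 20, mean = 0.1, year = 1993L),
    generate_speaker_counts(40, 20, mean = 0.3, year = 2007L))
  pts <- fit_betabinom_by_year(counts, bootstrap_reps = 50)
  expect_identical(pts$year, c(1993L, 2007L))
  expect_lt(pts$mle[1], pts$mle[2])
  expect_true(all(pts$ci_lo <= pts$mle & pts$mle <= pts$ci_hi))
})

test_that("ensemble intervals are mean plus/minus z times run spread", {
  expect_equal(unname(ensemble_interval(rep(0.4, 5))[c(1, 3, 4)]),
               c(0.4, 0.4, 0.4))
  iv <- ensemble_interval(c(0, 1))
  z <- qnorm(0.975)
  expect_equal(unname(iv[["mean"]]), 0.5)
  expect_equal(unname(iv[["ci_hi"]] - iv[["mean"]]), z * sqrt(0.5))
  set.seed(44)
  iv <- ensemble_interval(rnorm(1e4))
  expect_lt(abs(iv[["ci_lo"]] + 1.96), 0.05)
  expect_lt(abs(iv[["ci_hi"]] - 1.96), 0.05)
})

test_that("the overlap criterion needs coverage in every data year", {
  summ <- data.frame(year = c(1993, 2007), mean = c(0.1, 0.2),
                     sd = c(0.02, 0.02))
  summ$ci_lo <- summ$mean - 1.96 * summ$sd
  summ$ci_hi <- summ$mean + 1.96 * summ$sd
  mle <- data.frame(year = c(1993, 2007), mle = c(0.1, 0.2))
  expect_true(overlap_fit_check(summ, mle))
  mle2 <- data.frame(year = c(1993, 2007), mle = c(0.1, 0.25))
  expect_false(overlap_fit_check(summ, mle2))
  expect_identical(overlap_fit_check(summ, mle2[2:1, ]),
                   overlap_fit_check(summ, mle2))
  expect_error(overlap_fit_check(summ, data.frame(year = 1999, mle = 0.1)),
               "cover")
})

test_that("minimum-MSE selection picks the closest setting", {
  mle <- data.frame(year = 1:2, mle = c(0.1, 0.2))
  mk <- function(m1, m2) data.frame(year = 1:2, mean = c(m1, m2),
                                    sd = 0.01, ci_lo = 0, ci_hi = 1)
  sweep <- list(mk(0.2, 0.3),                  # mse 0.01
                mk(0.12, 0.26),                # mse 0.002
                mk(0.1 + 0.1, 0.2 + 0.2236068))  # mse 0.03
  attr(sweep, "mu_grid") <- c(0.01, 0.02, 0.03)
  sel <- select_min_mse(sweep, mle)
  expect_equal(sel$mse, c(0.01, 0.002, 0.03), tolerance = 1e-6)
  expect_identical(sel$mu, 0.02)

  ties <- list(mk(0.1, 0.2), mk(0.1, 0.2))
  attr(ties, "mu_grid") <- c(0.05, 0.01)
  expect_identical(select_min_mse(ties, mle)$mu, 0.01)
  expect_error(select_min_mse(list(), mle), "empty")
})

test_that("joint tail probabilities follow the normal model", {
  summ <- data.frame(year = c(1, 2), mean = c(0.2, 0.4), sd = c(0.1, 0.1))
  at <- function(z1, z2) data.frame(year = c(1, 2),
                                    mle = c(0.2 + z1 * 0.1, 0.4 + z2 * 0.1))
  expect_equal(joint_tail_probability(summ, at(0, 0)), 1.0)
  expect_equal(joint_tail_probability(summ, at(1.96, 1.96)), 0.0025,
               tolerance = 1e-3)
  expect_equal(joint_tail_probability(summ, at(1, 0)), 0.3173105,
               tolerance = 1e-4)
  expect_equal(joint_tail_probability(summ, at(-1, 0)),
               joint_tail_probability(summ, at(1, 0)))
  # one-sided halves each year's mass, including the exactly-central year
  expect_equal(joint_tail_probability(summ, at(1, 0), sided = "one"),
               (1 - pnorm(1)) * 0.5)
  # monotone in |z|, bounded in (0, 1]
  zs <- seq(0, 4, by = 0.5)
  ps <- vapply(zs, function(z) joint_tail_probability(summ, at(z, 0.3)),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  bad <- data.frame(year = 1:2, mean = c(0.2, 0.4), sd = c(0, 0.1))
  expect_error(joint_tail_probability(bad, at(0, 0)), "degenerate")
})
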