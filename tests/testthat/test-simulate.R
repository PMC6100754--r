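test_that("simulators are deterministic under a seed", {
  a1 <- simulate_arm(50, scale = 12, censor_rate = 0.02, seed = 3)
  a2 <- simulate_arm(50, scale = 12, censor_rate = 0.02, seed = 3)
  a3 <- simulate_arm(50, scale = 12, censor_rate = 0.02, seed = 4)
  expect_identical(a1$time, a2$time)
  expect_false(identical(a1$time, a3$time))
  s1 <- simulate_table(c(0.1, 0.2), c(0, 0.3), 0.2, c = 0.1, seed = 5)
  s2 <- simulate_table(c(0.1, 0.2), c(0, 0.3), 0.2, c = 0.1, seed = 5)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$truth$theta, s2$truth$theta)
})

test_that("simulated arms recover closed-form restricted means and ratios", {
  # exponential RMST: scale * (1 - exp(-h/scale))
  e <- rmst(km_fit(simulate_arm(2e4, scale = 10, seed = 14)), horizon = 10)
  expect_lt(abs(e$value - 10 * (1 - exp(-1))), 3 * e$se)
  # two large arms at a shared horizon approach the closed-form MR
  h <- 12
  eT <- rmst(km_fit(simulate_arm(2e4, scale = 15, seed = 15)), h)
  eC <- rmst(km_fit(simulate_arm(2e4, scale = 10, seed = 16)), h)
  mr_true <- (15 * (1 - exp(-h / 15))) / (10 * (1 - exp(-h / 10)))
  mr <- rmst_ratio(eT, eC)
  expect_lt(abs(mr$ln_mr - log(mr_true)), 3 * mr$se_ln_mr)
  # weibull arms are exercised end to end as well
  ew <- rmst(km_fit(simulate_arm(500, "weibull", scale = 10, shape = 1.4,
                                 censor_rate = 0.01, seed = 17)))
  expect_gt(ew$value, 0)
})

test_that("overwhelming censoring violates the arm invariants", {
  expect_error(simulate_arm(30, scale = 10, censor_rate = 1e7, seed = 18),
               "all-censored")
})

test_that("noiseless tables are exactly additive with equal relative potency", {
  alpha <- c(0.1, -0.2, 0.4)
  gamma <- c(0, 0.25, -0.1, 0.3)
  sim <- simulate_table(alpha, gamma, sigma_true = 0, c = 1e-9, seed = 19,
                        species = letters[1:3], interventions = LETTERS[1:4])
  expect_equal(sim$data$y, outer(alpha, gamma, "+"), tolerance = 1e-6,
               ignore_attr = TRUE)
  # ratio between two interventions preserved across species
  diffs <- sim$data$y[, 2] - sim$data$y[, 1]
  expect_lt(diff(range(diffs)), 1e-6)
})

test_that("simulated-cell variance decomposes into c^2 + sigma^2", {
  set.seed(20)
  alpha <- 0.2; gamma <- 0.1; sig <- 0.3; cc <- 0.15
  ys <- replicate(1e4, {
    th <- alpha + gamma + stats::rnorm(1, 0, sig)
    th + stats::rnorm(1, 0, cc)
  })
  expect_lt(abs(stats::var(ys) - (cc^2 + sig^2)), 0.05 * (cc^2 + sig^2))
  # the table generator exhibits the same marginal moments cellwise
  yy <- vapply(1:3000, function(k)
    simulate_table(alpha, gamma, sig, c = cc, seed = k)$data$y[1, 1], numeric(1))
  expect_lt(abs(stats::var(yy) - (cc^2 + sig^2)), 0.1 * (cc^2 + sig^2))
})

test_that("the paper-pattern mask matches the packaged grid", {
  m <- paper_mask()
  expect_equal(sum(m), 12)
  sim <- simulate_table(rep(0.1, 5), rep(0.2, 4), 0.2, c = 0.1, mask = m,
                        seed = 21)
  expect_equal(is.na(sim$data$y), !m, ignore_attr = TRUE)
})

test_that("well-specified recovery attains near-nominal coverage, misspecified skeptic stays directional", {
  pr <- prior_spec("gen", rep(0.2, 2), diag(0.3, 2), rep(0.1, 2), diag(0.3, 2))
  rec <- recovery_experiment(c(0.2, 0.25), c(0.1, 0.15), 0.25, pr,
                             replicates = 60, c = 0.12, seed = 22,
                             burn_in = 1500, draws = 3000, thin = 3)
  expect_gt(rec$coverage, 0.88)
  expect_lt(abs(rec$bias), 0.05)
  # zero-noise generation: posterior medians sit on the truth
  rec0 <- recovery_experiment(c(0.2, 0.25), c(0.1, 0.15), 0, pr,
                              replicates = 20, c = 0.02, seed = 23,
                              burn_in = 1500, draws = 3000, thin = 3)
  expect_lt(abs(rec0$bias), 0.02)
  # a skeptical prior on truly positive effects shrinks the estimate but the
  # bulk of the posterior still favors benefit when the data are precise
  sim <- simulate_table(rep(0.25, 5), rep(0.25, 4), 0.05, c = 0.08, seed = 24)
  fsp <- fast_fit(sim$data, "FSP", seed = 25)
  tab <- predict(fsp, SPECIES[1])
  expect_true(all(tab$median_mr < exp(0.5)))
  expect_true(all(tab$p_gt_1 > 0.5))
})
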