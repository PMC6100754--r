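empty_grid <- function(I = 2, J = 2, sd = 1) {
  evidence_matrix(matrix(NA_real_, I, J), matrix(sd, I, J),
                  species = paste0("s", 1:I), interventions = paste0("i", 1:J))
}

test_that("with no data the posterior reproduces the prior", {
  pr <- prior_spec("toy", c(0.2, -0.1), diag(c(0.5, 1)), c(0, 0.3),
                   diag(c(1, 0.8)))
  fit <- suppressWarnings(mrsynth(empty_grid(), pr, burn_in = 2000,
                                  draws = 160000, thin = 8, seed = 4))
  expect_lt(abs(mean(fit$draws$alpha[, 1]) - 0.2), 0.05)
  expect_lt(abs(stats::sd(fit$draws$alpha[, 1]) - sqrt(0.5)), 0.05)
  expect_lt(abs(mean(fit$draws$gamma[, 2]) - 0.3), 0.05)
  # truncated-at-zero sigma prior: N(0.5, 0.01) has negligible negative mass
  expect_lt(abs(stats::median(fit$draws$sigma) - 0.5), 0.01)
  expect_lt(abs(stats::sd(fit$draws$sigma) - 0.1), 0.01)
})

test_that("a flat single-cell model returns the measurement likelihood", {
  d <- evidence_matrix(matrix(0.5), matrix(0.2),
                       species = "s", interventions = "i")
  pr <- prior_spec("flat", 0, matrix(1e6), 0, matrix(1e6))
  fit <- mrsynth(d, pr, burn_in = 5000, draws = 100000, thin = 10,
                 seed = 8, sigma_fix = 0.05)
  th <- fit$draws$theta[, 1]
  expect_equal(mean(th), 0.5, tolerance = 0.02)
  expect_equal(stats::var(th), 0.04, tolerance = 0.006)
})

test_that("sampler matches the exact conjugate posterior on a 2x2 grid", {
  y <- matrix(c(0.4, 0.1, 0.7, NA), 2, 2)
  d <- evidence_matrix(y, matrix(0.15, 2, 2),
                       species = c("a", "b"), interventions = c("x", "z"))
  pr <- prior_spec("toy", c(0.1, 0), matrix(c(0.8, 0.2, 0.2, 0.6), 2),
                   c(0, 0.2), matrix(c(1, 0.3, 0.3, 0.9), 2))
  sig <- 0.3
  exact <- exact_two_way_posterior(d, pr, sig)
  fit <- mrsynth(d, pr, burn_in = 5000, draws = 200000, thin = 10,
                 seed = 5, sigma_fix = sig)
  bdraws <- cbind(fit$draws$alpha, fit$draws$gamma)
  # identified sums alpha_i + gamma_j
  for (i in 1:2) for (j in 1:2) {
    idx <- c(i, 2 + j)
    m_mc <- mean(rowSums(bdraws[, idx]))
    v_mc <- stats::var(rowSums(bdraws[, idx]))
    m_ex <- sum(exact$mean[idx])
    v_ex <- exact$cov[idx[1], idx[1]] + exact$cov[idx[2], idx[2]] +
      2 * exact$cov[idx[1], idx[2]]
    expect_lt(abs(m_mc - m_ex), 0.02)
    expect_lt(abs(v_mc - v_ex) / v_ex, 0.1)
  }
  # individual blocks too (regularized by the proper priors)
  expect_lt(max(abs(as.numeric(colMeans(bdraws)) - exact$mean)), 0.03)
})

test_that("data-free cells are summarized at least as uncertainly as observed ones", {
  fit <- fast_fit(load_table2(), "SP1", seed = 6, draws = 20000)
  tab <- predict(fit, "Humans", type = "cell")
  width <- log(tab$cri_high) - log(tab$cri_low)
  expect_gt(width[tab$intervention == "CR"], width[tab$intervention == "CR+"])
  expect_false(tab$observed[tab$intervention == "CR"])
})

test_that("summary nodes are ordered, labelled and probability-coherent", {
  fit <- fast_fit(load_table2(), "SP2", seed = 7)
  for (type in c("effect", "cell", "predictive")) {
    tab <- predict(fit, "Humans", type = type)
    expect_equal(tab$intervention, INTERVENTIONS)
    expect_true(all(tab$cri_low <= tab$median_mr & tab$median_mr <= tab$cri_high))
    expect_true(all(tab$p_gt_1 >= 0 & tab$p_gt_1 <= 1))
  }
  expect_error(predict(fit, "Martians"), "unknown species")
  # symmetric prior, no data: P(MR > 1) is one half
  pfit <- suppressWarnings(mrsynth(empty_grid(), prior_spec(
    "sym", c(0, 0), diag(2), c(0, 0), diag(2)),
    burn_in = 1000, draws = 20000, thin = 2, seed = 9))
  expect_equal(predict(pfit, "s1")$p_gt_1, rep(0.5, 2), tolerance = 0.02)
})

test_that("chains started from different seeds agree at reference lengths", {
  f1 <- mrsynth(load_table2(), "SP2", seed = 101)
  f2 <- mrsynth(load_table2(), "SP2", seed = 202)
  m1 <- log(predict(f1, "Humans")$median_mr)
  m2 <- log(predict(f2, "Humans")$median_mr)
  expect_lt(max(abs(m1 - m2)), 0.02)
  expect_lt(abs(stats::median(f1$draws$sigma) - stats::median(f2$draws$sigma)),
            0.02)
  # and the same seed reproduces the run exactly
  f3 <- mrsynth(load_table2(), "SP2", seed = 101)
  expect_identical(f1$draws, f3$draws)
})

test_that("sigma proposal tunes into the target acceptance band", {
  fit <- mrsynth(load_table2(), "SP1", profile = "fast", seed = 10)
  expect_gt(fit$sigma_acc_rate, 0.15)
  expect_lt(fit$sigma_acc_rate, 0.6)
})

test_that("invalid configurations are rejected", {
  expect_error(mrsynth(load_table2(), make_prior("SP1"), burn_in = -1),
               "schedule")
  pr2 <- prior_spec("small", 0, diag(1), 0, diag(1))
  expect_error(mrsynth(load_table2(), pr2), "dimensions")
  expect_warning(mrsynth(empty_grid(), prior_spec("p", c(0, 0), diag(2),
                                                  c(0, 0), diag(2)),
                         burn_in = 100, draws = 4000, thin = 2),
                 "prior")
})

test_that("accessor methods expose coherent posterior summaries", {
  fit <- fast_fit(load_table2(), "EP", seed = 12)
  co <- coef(fit)
  expect_named(co, c("alpha", "gamma", "sigma"))
  expect_length(co$alpha, 5)
  expect_gt(co$sigma, 0)
  r <- residuals(fit)
  expect_true(all(is.na(r[!fit$data$obs])))
  expect_true(all(abs(r[fit$data$obs]) < 10))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(is.na(sims[[1]]), !fit$data$obs)
  s <- summary(fit)
  expect_s3_class(s, "summary.mrsynth")
  expect_output(print(s), "sigma")
})
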