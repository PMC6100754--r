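test_that("product-limit estimate matches hand calculations", {
  # no censoring: S drops by 1/n at each event
  k <- km_fit(surv_arm(c(2, 4, 6), c(1, 1, 1)))
  expect_equal(k$time, c(2, 4, 6))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  # censoring reduces the later risk set: (1, 2+, 3)
  k2 <- km_fit(surv_arm(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(k2$time, c(1, 3))
  expect_equal(k2$surv, c(2 / 3, 0))
  # single event
  expect_equal(km_fit(surv_arm(5, 1))$surv, 0)
})

test_that("degenerate arms are rejected", {
  expect_error(surv_arm(numeric(0), integer(0)), "empty")
  expect_error(surv_arm(c(1, 2), c(0, 0)), "all-censored")
  expect_error(surv_arm(c(0, 1), c(1, 1)), "> 0")
  expect_error(rmst(km_fit(surv_arm(1, 1)), horizon = -1), "horizon")
  expect_error(rmst(km_fit(surv_arm(1, 1)), horizon = 2), "exceeds")
})

test_that("RMST value and Greenwood-type se match hand integration", {
  # complete follow-up at the last time: RMST is the sample mean
  e <- rmst(km_fit(surv_arm(c(2, 4, 6), c(1, 1, 1))))
  expect_equal(e$value, 4)
  # censored toy: 1*1 + (2/3)*2; var = (4/3)^2 * 1/(3*2)
  e2 <- rmst(km_fit(surv_arm(c(1, 2, 3), c(1, 0, 1))))
  expect_equal(e2$value, 7 / 3)
  expect_equal(e2$se, sqrt((4 / 3)^2 / 6))
  # large-sample exponential arm approaches the closed form
  arm <- simulate_arm(1e5, scale = 10, seed = 11)
  e3 <- rmst(km_fit(arm), horizon = 10)
  expect_lt(abs(e3$value - 10 * (1 - exp(-1))), 3 * e3$se)
})

test_that("RMST equals the sample mean without censoring and grows with horizon", {
  set.seed(42)
  for (r in 1:20) {
    n <- sample(3:40, 1)
    tt <- stats::rexp(n, 0.2) + 0.01
    k <- km_fit(surv_arm(tt, rep(1, n)))
    expect_equal(rmst(k)$value, mean(tt), tolerance = 1e-12)
    expect_true(all(diff(k$surv) <= 1e-12))
    hs <- sort(stats::runif(4, min(tt), max(tt)))
    vals <- vapply(hs, function(h) rmst(k, h)$value, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("KM and RMST agree with the survival-package oracle to 1e-10", {
  skip_if_not_installed("survival")
  set.seed(3)
  for (r in 1:100) {
    arm <- random_arm(sample(5:80, 1))
    k <- km_fit(arm)
    e <- rmst(k)
    f <- survival::survfit(survival::Surv(arm$time, arm$event) ~ 1)
    sf <- summary(f, times = k$time)$surv
    tab <- summary(f, rmean = max(arm$time))$table
    expect_lt(max(abs(k$surv - sf)), 1e-10)
    expect_lt(abs(e$value - tab[["rmean"]]), 1e-10)
    expect_lt(abs(e$se - tab[["se(rmean)"]]), 1e-10)
  }
})

test_that("delta-method se of ln(MR) agrees with a bootstrap oracle", {
  set.seed(9)
  armT <- random_arm(60, event_rate = 0.08)
  armC <- random_arm(60, event_rate = 0.12)
  # fixed horizons deep inside each arm's support so every resample covers them
  hT <- stats::quantile(armT$time, 0.6)
  hC <- stats::quantile(armC$time, 0.6)
  mr <- rmst_ratio(rmst(km_fit(armT), hT), rmst(km_fit(armC), hC))
  boot <- replicate(600, {
    iT <- sample.int(60, replace = TRUE); iC <- sample.int(60, replace = TRUE)
    if (!any(armT$event[iT]) || !any(armC$event[iC])) return(NA_real_)
    aT <- surv_arm(armT$time[iT], armT$event[iT])
    aC <- surv_arm(armC$time[iC], armC$event[iC])
    if (max(aT$time) < hT || max(aC$time) < hC) return(NA_real_)
    log(rmst(km_fit(aT), hT)$value / rmst(km_fit(aC), hC)$value)
  })
  bsd <- stats::sd(boot, na.rm = TRUE)
  expect_lt(abs(mr$se_ln_mr - bsd) / bsd, 0.15)
})

test_that("RMST ratio reproduces the published human rows and the identity case", {
  han <- rmst_ratio(c(41.36, 4.02), c(23.70, 2.85))
  expect_equal(round(han$mr, 2), 1.75)
  expect_equal(round(han$se_mr, 2), 0.27)
  rieger <- rmst_ratio(c(7.25, 1.07), c(5.16, 1.29))
  expect_equal(round(rieger$mr, 2), 1.41)
  expect_equal(round(rieger$se_mr, 2), 0.41)
  id <- rmst_ratio(c(3, 0), c(3, 0))
  expect_equal(id$mr, 1)
  expect_equal(id$se_mr, 0)
  expect_equal(id$ln_mr, 0)
  expect_error(rmst_ratio(c(-1, 0.1), c(1, 0.1)), "positive")
})

test_that("survival tables round-trip through the reader and summary", {
  tmp <- tempfile(fileext = ".csv")
  set.seed(5)
  df <- NULL
  for (sid in c("s1", "s2")) for (a in c("treatment", "control")) {
    arm <- random_arm(12)
    df <- rbind(df, data.frame(study_id = sid, arm = a,
                               time = arm$time, event = arm$event))
  }
  utils::write.csv(df, tmp, row.names = FALSE)
  tab <- rmst_table(tmp)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$mr[1], tab$rmst[1] / tab$rmst[2])
  expect_equal(tab$se_ln_mr[1],
               sqrt((tab$se[1] / tab$rmst[1])^2 + (tab$se[2] / tab$rmst[2])^2))
  # shared horizon makes both arms use the smaller last time
  tab2 <- rmst_table(tmp, shared_horizon = TRUE)
  expect_equal(tab2$horizon[1], tab2$horizon[2])
  unlink(tmp)
})
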