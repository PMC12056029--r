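test_that("one_group_discrete matches the goodness-of-fit closed form", {
  ch <- disc_cohort(rep(c("A", "B", "C"), each = 30))
  r <- one_group_discrete(ch, "g")
  expect_equal(r$test$statistic, 0)
  expect_equal(r$test$p_value, 1)

  ch2 <- disc_cohort(rep(c("A", "B", "C"), times = c(10, 20, 30)))
  r2 <- one_group_discrete(ch2, "g")
  expect_equal(r2$test$statistic, 10)  # (100 + 0 + 100) / 20
  expect_equal(r2$test$degrees_of_freedom, 2)
  expect_equal(r2$test$p_value, pchisq(10, 2, lower.tail = FALSE))

  # expected_probs equal to observed proportions: statistic 0
  r3 <- one_group_discrete(ch2, "g",
                           expected_probs = c(A = 1/6, B = 2/6, C = 3/6))
  expect_equal(r3$test$statistic, 0)
  expect_error(one_group_discrete(disc_cohort(rep("A", 5)), "g"),
               "single observed level")
})

test_that("two_group_discrete equals the 2x2 closed form and chisq.test oracle", {
  a <- disc_cohort(rep(c("yes", "no"), c(10, 20)))
  b <- disc_cohort(rep(c("yes", "no"), c(20, 10)))
  r <- two_group_discrete(a, b, "g")
  expect_equal(r$test$statistic, 60 * (10 * 10 - 20 * 20)^2 / 30^4,
               tolerance = 1e-12)
  expect_equal(r$test$degrees_of_freedom, 1)

  # identical distributions: statistic 0, p = 1
  r0 <- two_group_discrete(a, a, "g")
  expect_equal(r0$test$statistic, 0)
  expect_equal(r0$test$p_value, 1)

  # a level absent in one group enters with count 0
  c1 <- disc_cohort(c("A", "A", "B", "B"))
  c2 <- disc_cohort(c("A", "B", "C", "C"))
  r2 <- two_group_discrete(c1, c2, "g")
  expect_equal(unname(r2$table["a", "C"]), 0)
  expect_equal(r2$test$degrees_of_freedom, 2)

  # oracle: stats::chisq.test without correction, across random tables
  set.seed(17)
  for (i in 1:10) {
    na <- sample(10:40, 2); nb <- sample(10:40, 2)
    ga <- disc_cohort(rep(c("x", "y"), na))
    gb <- disc_cohort(rep(c("x", "y"), nb))
    mine <- two_group_discrete(ga, gb, "g")
    orc <- suppressWarnings(
      stats::chisq.test(rbind(na, nb), correct = FALSE))
    expect_equal(mine$test$statistic, unname(orc$statistic), tolerance = 1e-10)
    expect_equal(mine$test$p_value, unname(orc$p.value), tolerance = 1e-10)
    # Yates correction parity on 2x2
    mine_y <- two_group_discrete(ga, gb, "g", continuity_correction = TRUE)
    orc_y <- suppressWarnings(stats::chisq.test(rbind(na, nb), correct = TRUE))
    expect_equal(mine_y$test$statistic, unname(orc_y$statistic),
                 tolerance = 1e-10)
  }
})

test_that("two_group_continuous matches textbook and t.test oracles", {
  a <- cont_cohort(v = c(1, 2, 3))
  b <- cont_cohort(v = c(4, 5, 6))
  r <- two_group_continuous(a, b, "v", variance_mode = "pooled")
  expect_equal(r$test_name, "two-sample t-test (pooled)")
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$degrees_of_freedom, 4)
  expect_equal(r$effect_summary$mean_difference, -3)

  # identical groups: statistic 0, p = 1
  r0 <- two_group_continuous(a, a, "v")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # order invariance
  b2 <- cont_cohort(v = c(3, 1, 2))
  expect_equal(two_group_continuous(a, b2, "v")$statistic, 0)

  set.seed(23)
  for (i in 1:10) {
    xa <- rnorm(sample(5:30, 1)); xb <- rnorm(sample(5:30, 1), 0.5, 1.5)
    ca <- cont_cohort(v = xa); cb <- cont_cohort(v = xb)
    mine <- two_group_continuous(ca, cb, "v", variance_mode = "welch")
    orc <- stats::t.test(xa, xb)
    expect_equal(mine$statistic, unname(orc$statistic), tolerance = 1e-10)
    expect_equal(mine$degrees_of_freedom, unname(orc$parameter),
                 tolerance = 1e-10)
    expect_equal(mine$p_value, orc$p.value, tolerance = 1e-10)
    # sign flips under exchange, p invariant
    flip <- two_group_continuous(cb, ca, "v")
    expect_equal(flip$statistic, -mine$statistic)
    expect_equal(flip$p_value, mine$p_value)
  }
  expect_error(two_group_continuous(cont_cohort(v = c(2, 2)),
                                    cont_cohort(v = c(2, 2)), "v"),
               "undefined")
})

test_that("km_estimate matches hand computation and survival oracle", {
  # no censoring: empirical survivor function
  km <- km_estimate(tte_cohort(c(1, 2, 3), c(1, 1, 1)), "t")
  expect_equal(km$survival, c(2/3, 1/3, 0))

  # censored worked example: S(1) = 2/3, S(3) = 0
  km2 <- km_estimate(tte_cohort(c(1, 2, 3), c(1, 0, 1)), "t")
  expect_equal(km2$event_times, c(1, 3))
  expect_equal(km2$survival, c(2/3, 0))
  expect_equal(km2$censoring_times, 2)

  # all censored: survival identically 1
  km3 <- km_estimate(tte_cohort(c(1, 2), c(0, 0)), "t")
  expect_length(km3$event_times, 0)

  skip_if_not_installed("survival")
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    time <- round(rexp(n, 0.5), 2)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(tte_cohort(time, event), "t")
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    orc_t <- sf$time[sf$n.event > 0]
    orc_s <- sf$surv[sf$n.event > 0]
    expect_equal(km$event_times, orc_t)
    expect_equal(km$survival, orc_s, tolerance = 1e-12)
  }
})

test_that("KM is non-increasing and matches a brute-force product oracle", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    time <- sample(1:6, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    km <- km_estimate(tte_cohort(time, event), "t")
    expect_true(all(diff(c(1, km$survival)) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    # brute force: iterate distinct event times, count risk sets directly
    s <- 1
    for (tt in sort(unique(time[event == 1]))) {
      d <- sum(time == tt & event == 1)
      atr <- sum(time >= tt)
      s <- s * (1 - d / atr)
      expect_equal(km$survival[km$event_times == tt], s)
    }
  }
})

test_that("two_group_tte log-rank matches survdiff and is symmetric", {
  a <- tte_cohort(c(1, 2), c(1, 1))
  b <- tte_cohort(c(3, 4), c(1, 1))
  r <- two_group_tte(a, b, "t")
  # hypergeometric expectations: 2/4 at t=1, 1/3 at t=2, 0 after
  expect_equal(r$test$effect_summary$expected_a, 1/2 + 1/3, tolerance = 1e-12)
  expect_equal(r$test$effect_summary$observed_a, 2)

  # identical groups: statistic 0, p = 1
  r0 <- two_group_tte(a, a, "t")
  expect_equal(r0$test$statistic, 0)
  expect_equal(r0$test$p_value, 1)

  skip_if_not_installed("survival")
  set.seed(55)
  for (i in 1:10) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    ta <- rexp(na, 0.5); tb <- rexp(nb, 0.9)
    ea <- rbinom(na, 1, 0.8); eb <- rbinom(nb, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) ea[1] <- 1
    mine <- two_group_tte(tte_cohort(ta, ea), tte_cohort(tb, eb), "t")
    orc <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(na, nb)))
    expect_equal(mine$test$statistic, orc$chisq, tolerance = 1e-10)
    # group relabeling leaves the statistic unchanged
    flip <- two_group_tte(tte_cohort(tb, eb), tte_cohort(ta, ea), "t")
    expect_equal(flip$test$statistic, mine$test$statistic, tolerance = 1e-10)
    # monotone time transform leaves it unchanged
    tr <- two_group_tte(tte_cohort(exp(ta), ea), tte_cohort(exp(tb), eb), "t")
    expect_equal(tr$test$statistic, mine$test$statistic, tolerance = 1e-10)
  }
  expect_error(two_group_tte(tte_cohort(1:2, c(0, 0)),
                             tte_cohort(1:2, c(0, 0)), "t"),
               "no events")
})

test_that("one_group_continuous mirrors the univariate conventions", {
  r <- one_group_continuous(cont_cohort(v = c(5, 5, 5)), "v")
  expect_equal(r$summary$mean, 5)
  expect_equal(r$summary$sd, 0)
  r2 <- one_group_continuous(cont_cohort(v = 1:5), "v")
  expect_equal(r2$summary$mean, 3)
  expect_equal(r2$summary$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(r2$boxplot$median, 3)
  empty <- cohort(data.frame(v = NA_real_))
  expect_error(one_group_continuous(empty, "v"), "no complete rows")
})
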