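test_that("KM equals the empirical survival function when nothing is censored", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  set.seed(4)
  t <- round(rexp(40, 0.2), 2)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$survival, emp)
})

test_that("KM matches the hand-computed product-limit table on a mixed toy set", {
  toy <- toy_survival_fixture()  # events at 1,3,4,6; censored at 2,5
  km <- km_estimate(toy$time, toy$event)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 4, 6))
  expect_equal(ev$survival, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
  expect_equal(ev$n_risk, c(6, 4, 3, 1))
})

test_that("KM survival starts at 1, is non-increasing, and all-censored data stay at 1", {
  set.seed(9)
  km <- km_estimate(rexp(30), rbinom(30, 1, 0.5))
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival <= 1 & km$survival >= 0))
  kmc <- km_estimate(1:5, rep(0, 5))
  expect_true(all(kmc$survival == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank is zero for identical groups and detects full separation", {
  t <- c(1, 2, 3, 4, 5); e <- c(1, 1, 0, 1, 1)
  res0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)
  sep <- logrank_test(c(1:20, 101:120), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_lt(sep$p_value, 0.01)
})

test_that("two-group log-rank equals the squared standardized O-E sum", {
  # direct computation from the risk-set definition
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  grp <- c("a", "b", "a", "b", "a", "b", "a", "b")
  res <- logrank_test(time, event, grp)
  o_minus_e <- 0; v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at_risk <- time >= u
    d <- sum(event == 1 & time == u)
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "a")
    d1 <- sum(event == 1 & time == u & grp == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$statistic, o_minus_e^2 / v)
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "at least one event")
})

test_that("Cox HR on a binary covariate approximates the exponential rate ratio", {
  set.seed(22)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  rate <- ifelse(x == 1, 0.30, 0.10)
  d <- data.frame(x = x, time = rexp(n, rate), event = 1)
  fit <- cox_fit(d, "time", "event", "x")
  rate_ratio <- (sum(d$event[x == 1]) / sum(d$time[x == 1])) /
    (sum(d$event[x == 0]) / sum(d$time[x == 0]))
  expect_equal(fit$table$hr, rate_ratio, tolerance = 0.1)
  expect_true(fit$converged)
})

test_that("Cox Wald CI covers 1 for a null covariate in most simulations", {
  set.seed(23)
  cover <- 0
  for (i in 1:100) {
    n <- 150
    d <- data.frame(x = rnorm(n), time = rexp(n, 0.1),
                    event = rbinom(n, 1, 0.8))
    f <- cox_fit(d, "time", "event", "x")
    cover <- cover + (f$table$ci_low <= 1 && 1 <= f$table$ci_high)
  }
  expect_gte(cover, 93)
})

test_that("multivariate entry keeps exactly the univariately significant terms, in order", {
  ur <- data.frame(term = c("a", "b", "c", "d"),
                   p_value = c(0.2, 0.01, 0.04, NA))
  expect_equal(select_multivariate_covariates(ur), c("b", "c"))
  expect_equal(select_multivariate_covariates(ur, alpha = 1), c("a", "b", "c"))
  expect_equal(select_multivariate_covariates(
    data.frame(term = "a", p_value = 0.9)), character(0))
})

test_that("stromal type ordinal coding follows the prognostic ordering", {
  expect_equal(stromal_type_code(c("inflammatory", "intermediate",
                                   "fibrotic", "necrotic")), 0:3)
  expect_error(stromal_type_code("stromal"), "unknown stromal type")
})
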