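test_that("Pearson chi-square (no continuity correction) matches the 2x2 closed form", {
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(sample(1:50, 4, replace = TRUE), 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    res <- pearson_chi2(m)
    expect_equal(res$statistic, closed)
    expect_equal(res$p_value, pchisq(closed, 1, lower.tail = FALSE))
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
  # independence: statistic 0, p = 1
  r0 <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Fisher's exact test reproduces enumeration on worked examples", {
  expect_equal(fisher_exact(matrix(c(2, 3, 3, 2), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  # degenerate margin: only one possible table
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact(matrix(1, 3, 3)), "2 x 2")
})

test_that("Fisher's exact test agrees with stats::fisher.test on random tables", {
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact(m)$p_value, fisher.test(m)$p.value, tolerance = 1e-8)
  }
})

test_that("test selection uses Fisher below expected count 5 on 2x2, else chi-square", {
  big <- matrix(c(20, 114, 17, 34), 2, byrow = TRUE)  # min expected ~10.2
  expect_equal(select_and_test(big)$method, "pearson_chi2")
  small <- matrix(c(1, 9, 2, 8), 2, byrow = TRUE)     # expected 1.5 < 5
  expect_equal(select_and_test(small)$method, "fisher_exact")
  rc <- matrix(c(1, 2, 3, 30, 20, 10), 2, byrow = TRUE)
  expect_warning(res <- select_and_test(rc), "Pearson")
  expect_equal(res$method, "pearson_chi2")
})

test_that("Spearman correlation handles concordance, discordance, ties and constants", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1)
  # tie-heavy vectors: matches the average-rank definition computed directly
  x <- c(1, 1, 2, 3, 3, 3); y <- c(2, 1, 1, 5, 5, 4)
  rho_def <- cor(rank(x), rank(y))
  expect_equal(spearman_correlation(x, y)$rho, rho_def)
  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_correlation(exp(a), b)$rho, spearman_correlation(a, b)$rho)
  expect_warning(res <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
})

test_that("Kruskal-Wallis matches hand-computed H and handles degenerate input", {
  # ranks 1..6 in two clean groups: H = 12/42 * 27/2 = 27/7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7)
  expect_equal(res$p_value, pchisq(27 / 7, 1, lower.tail = FALSE))
  # three disjoint-range groups of 3: maximal H for the design
  res3 <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res3$statistic, 7.2)
  # identical observations: H defined as 0, p = 1
  res0 <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
  # vector + factor interface agrees with the list interface
  resv <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(resv$statistic, res$statistic)
})

test_that("logistic OR on one binary covariate equals the cross-product ratio", {
  # reconstruct individual records from a 2x2 table
  m <- matrix(c(20, 114, 17, 34), 2, byrow = TRUE,
              dimnames = list(c("yes", "no"), c("good", "poor")))
  d <- data.frame(
    response = rep(rep(c("good", "poor"), 2), c(20, 17, 114, 34)),
    exposed = rep(c(1, 0), c(37, 148)))
  fit <- logistic_fit(d, "response", "exposed")
  emp_or <- (20 * 34) / (114 * 17)  # odds(good|exposed) / odds(good|unexposed)
  expect_equal(fit$table$or, emp_or, tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("logistic Wald CI covers 1 for a null covariate in most simulations", {
  set.seed(14)
  cover <- 0
  for (i in 1:100) {
    d <- data.frame(response = sample(c("good", "poor"), 400, replace = TRUE),
                    x = rnorm(400))
    f <- logistic_fit(d, "response", "x")
    cover <- cover + (f$table$ci_low <= 1 && 1 <= f$table$ci_high)
  }
  expect_gte(cover, 93)
})

test_that("separation is detected and flagged", {
  d <- data.frame(response = rep(c("good", "poor"), each = 10),
                  x = rep(c(1, 0), each = 10))
  f <- logistic_fit(d, "response", "x")
  expect_true(f$separation)
})

test_that("multivariate mode admits only univariately significant covariates", {
  set.seed(15)
  n <- 400
  y <- rbinom(n, 1, 0.6)
  d <- data.frame(response = ifelse(y == 1, "good", "poor"),
                  signal = y + rnorm(n, sd = 0.8),
                  noise = rnorm(n))
  f <- logistic_fit(d, "response", c("signal", "noise"), mode = "multivariate")
  expect_equal(f$covariates, "signal")
})

test_that("build_table1 reproduces cohort marginals, percentages and per-variable tests", {
  d <- data.frame(
    response = factor(rep(c("good", "poor"), c(134, 51)), levels = c("good", "poor")),
    ln = c(rep(c("yes", "no"), c(20, 114)), rep(c("yes", "no"), c(17, 34))))
  t1 <- build_table1(d, "ln", "response")
  all_cases <- t1[t1$variable == "All cases", ]
  expect_equal(all_cases$n_total, 185)
  expect_equal(all_cases$pct_good, 72.4)
  expect_equal(all_cases$pct_poor, 27.6)
  yes <- t1[t1$level == "yes", ]
  expect_equal(yes$n_good, 20); expect_equal(yes$pct_good, 14.9)
  expect_equal(yes$n_poor, 17); expect_equal(yes$pct_poor, 33.3)
  p <- t1$p_value[t1$variable == "ln"][1]
  expect_equal(round(p, 3), 0.005)
  # missing values get an explicit NA row, excluded from the test
  d$hpv <- d$ln; d$hpv[1:40] <- NA
  t2 <- build_table1(d, c("ln", "hpv"), "response")
  expect_true("NA" %in% t2$level[t2$variable == "hpv"])
  expect_error(build_table1(d[d$response == "good", ], "ln", "response"),
               "2 levels|empty stratum")
})

test_that("printed percentages are count/column-total rounded half-up to 1 decimal", {
  set.seed(16)
  d <- data.frame(response = sample(c("good", "poor"), 77, replace = TRUE),
                  v = sample(c("a", "b", "c"), 77, replace = TRUE))
  t1 <- build_table1(d, "v", "response")
  n_g <- sum(d$response == "good"); n_p <- sum(d$response == "poor")
  vr <- t1[t1$variable == "v", ]
  expect_equal(vr$pct_good, floor(1000 * vr$n_good / n_g + 0.5) / 10)
  expect_equal(vr$pct_poor, floor(1000 * vr$n_poor / n_p + 0.5) / 10)
})
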