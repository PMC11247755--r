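test_that("TILV is the stroma x TILs percent product", {
  expect_identical(compute_tilv(30, 80), 2400)
  expect_identical(compute_tilv(50, 5), 250)
  expect_identical(compute_tilv(0, 90), 0)
  expect_error(compute_tilv(101, 50), "\\[0, 100\\]")
})

test_that("TILV is symmetric and bilinear", {
  set.seed(2)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(compute_tilv(a, b), compute_tilv(b, a))
  expect_equal(compute_tilv(a / 2, b), compute_tilv(a, b) / 2)
  expect_equal(compute_tilv(a, b / 4), compute_tilv(a, b) / 4)
})

test_that("stromal TILs grading uses (<=5, (5,50], >50]", {
  expect_equal(as.character(grade_stromal_tils(c(5, 50, 50.5, 0, 100))),
               c("low", "intermediate", "high", "low", "high"))
  expect_error(grade_stromal_tils(-2), "\\[0, 100\\]")
})

test_that("IHC density is mean HPF count over field area, and is linear", {
  expect_equal(compute_ihc_density(c(30, 40, 50), 0.24), 40 / 0.24)
  expect_equal(compute_ihc_density(c(24, 24, 24), 0.24), 100)
  expect_equal(compute_ihc_density(c(0, 0, 0), 0.5), 0)
  expect_error(compute_ihc_density(c(1, 2), 0.24), "exactly 3")
  expect_error(compute_ihc_density(c(1, 2, 3), 0), "positive")
  cnt <- matrix(rpois(30, 20), ncol = 3)
  expect_equal(compute_ihc_density(2 * cnt, 0.3),
               2 * compute_ihc_density(cnt, 0.3))
  expect_equal(compute_ihc_density(cnt, 0.15),
               2 * compute_ihc_density(cnt, 0.3))
})

test_that("ratio markers compute CD4/CD8 and CD8/FOXP3 with high/low calls", {
  r <- compute_ratio_markers(cd8_density = 100, cd4_density = 300,
                             foxp3_density = 100)
  expect_equal(r$cd4_cd8_ratio, 3)
  expect_equal(as.character(r$cd4_cd8_high), "high")   # 3 > 2.17
  expect_equal(r$cd8_foxp3_ratio, 1)
  expect_equal(as.character(r$cd8_foxp3_high), "low")  # 1 <= 5.24
  r2 <- compute_ratio_markers(524.0001, 10, 100)
  expect_equal(as.character(r2$cd8_foxp3_high), "high")
  # degenerate denominators
  r3 <- compute_ratio_markers(cd8_density = 0, cd4_density = 5, foxp3_density = 0)
  expect_true(is.infinite(r3$cd4_cd8_ratio))  # 5/0 -> Inf
  expect_true(is.na(r3$cd8_foxp3_ratio))      # 0/0 -> missing
  r4 <- compute_ratio_markers(0, 0, 0)
  expect_true(is.na(r4$cd4_cd8_ratio))
  expect_error(compute_ratio_markers(-1, 1, 1), "nonnegative")
})

test_that("PD-L1 scores follow the CPS/TPS/IPS formulas with the cap and >=1 positivity", {
  s <- compute_pdl1_scores(10, 5, 100, 50)
  expect_equal(s$cps, 15); expect_true(s$cps_pos)
  expect_equal(s$tps, 10); expect_equal(s$ips, 10)
  s0 <- compute_pdl1_scores(0, 0, 100, 50)
  expect_equal(s0$tps, 0); expect_false(s0$tps_pos)
  scap <- compute_pdl1_scores(200, 50, 100, 50)
  expect_equal(scap$cps, 100)
  # zero denominator -> missing, not zero
  sz <- compute_pdl1_scores(5, 5, 0, 0)
  expect_true(is.na(sz$cps)); expect_true(is.na(sz$ips))
})

test_that("CPS/TPS are monotone in positive counts at fixed denominators", {
  ks <- 0:60
  s <- compute_pdl1_scores(ks, 2, 100, 50)
  expect_true(all(diff(s$cps) >= 0))
  expect_true(all(diff(s$tps) >= 0))
  expect_true(all(diff(as.integer(s$cps_pos)) >= 0))
})

test_that("Youden cutpoint matches the exhaustive oracle on worked examples", {
  res <- youden_cutoff(c(0.9, 0.8, 0.7, 0.2, 0.1),
                       c("good", "good", "good", "poor", "poor"))
  expect_equal(res$cutoff, 0.2)
  expect_equal(res$youden, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  # identical distributions: J = 0 everywhere, smallest cutoff returned
  resnull <- youden_cutoff(c(1, 2, 3, 1, 2, 3),
                           rep(c("good", "poor"), each = 3))
  expect_equal(resnull$youden, 0)
  expect_equal(resnull$cutoff, 1)
  res3 <- youden_cutoff(c(1, 3, 5, 2, 4, 6), rep(c("good", "poor"), each = 3))
  oracle <- youden_bruteforce(c(1, 3, 5, 2, 4, 6), rep(c("good", "poor"), each = 3))
  expect_equal(res3$cutoff, oracle$cutoff)
  expect_equal(res3$youden, oracle$youden)
  expect_error(youden_cutoff(1:3, rep("good", 3)), "both classes")
})

test_that("Youden cutpoint equals exhaustive search on 200 random small datasets", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    v <- round(rnorm(n, sample(0:3, 1)), 1)
    lab <- sample(c("good", "poor"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("good", "poor")
    got <- youden_cutoff(v, lab)
    want <- youden_bruteforce(v, lab)
    expect_identical(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$youden)
  }
})

test_that("dichotomization is strict-above with missingness propagated", {
  x <- dichotomize_marker(c(76, 75, NA), 75)
  expect_equal(as.character(x), c("high", "low", NA))
  expect_error(dichotomize_marker(1:3, Inf), "finite")
  # fraction high equals the empirical survival function just above the cutoff
  set.seed(5)
  v <- sample(0:200, 300, replace = TRUE)
  cut <- 75
  expect_equal(mean(dichotomize_marker(v, cut) == "high"), mean(v > cut))
})
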