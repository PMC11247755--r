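test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n = 120)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "slides"), attr(b, "slides"))
  c_ <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$viable_pct, c_$viable_pct))
})

test_that("configuration validation rejects invalid mixtures and hazards", {
  expect_error(cohort_config(response_probs = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(cohort_config(stromal_type_probs = c(0.5, 0.4, 0.2, -0.1)),
               "probability 4-vector")
  expect_error(cohort_config(n = 2), "n >= 4")
  expect_error(cohort_config(baseline_hazard_dfs = 0.001,
                             baseline_hazard_os = 0.002), "DFS hazard")
})

test_that("every generated slide and patient composition is a valid tumor bed", {
  co <- generate_cohort(cohort_config(n = 150), seed = 8)
  slides <- attr(co, "slides")
  m <- as.matrix(slides[, c("viable_pct", "necrosis_pct",
                            "inflammatory_pct", "fibrotic_pct")])
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), rep(100, nrow(m)), tolerance = 1e-9)
  mp <- as.matrix(co[, c("viable_pct", "necrosis_pct",
                         "inflammatory_pct", "fibrotic_pct")])
  expect_true(all(mp >= 0))
  expect_equal(unname(rowSums(mp)), rep(100, nrow(co)), tolerance = 1e-9)
  # viable percentage consistent with the recorded grade
  expect_identical(as.character(co$grade),
                   as.character(classify_pathological_response(co$viable_pct)))
})

test_that("default grade frequencies stay inside the multinomial 99% envelope", {
  probs <- c(27, 49, 58, 51) / 185
  for (seed in c(2, 13, 31)) {
    co <- generate_cohort(cohort_config(n = 185), seed = seed)
    counts <- as.integer(table(co$grade))
    lo <- qbinom(0.005, 185, probs)
    hi <- qbinom(0.995, 185, probs)
    expect_true(all(counts >= lo & counts <= hi),
                info = sprintf("seed %d: %s", seed, paste(counts, collapse = "/")))
  }
})

test_that("TILV values are consistent with the generated high/low indicator", {
  co <- generate_cohort(cohort_config(n = 400), seed = 10)
  expect_equal(co$tilv, co$stroma_pct * co$stromal_tils_pct)
  expect_identical(co$tilv_high == 1, co$tilv > 75)
})

test_that("null TILV link yields OR confidence intervals covering 1", {
  cfg <- cohort_config(n = 300, tilv_or = 1)
  cover <- 0
  for (seed in 1:60) {
    co <- generate_cohort(cfg, seed = seed)
    f <- logistic_fit(co, "response", "tilv_high")
    cover <- cover + (f$table$ci_low <= 1 && 1 <= f$table$ci_high)
  }
  expect_gte(cover / 60, 0.93)
})

test_that("realized OS censoring fraction is within 5 points of the target", {
  for (rate in c(0.2, 0.3, 0.5)) {
    co <- generate_cohort(cohort_config(n = 1000, censor_rate = rate), seed = 17)
    expect_lt(abs(mean(co$os_event == 0) - rate), 0.05)
  }
})

test_that("dfs_time never exceeds os_time", {
  co <- generate_cohort(cohort_config(n = 500), seed = 19)
  expect_true(all(co$dfs_time <= co$os_time + 1e-12))
})

test_that("survival ordering across stromal types matches the generating hazards", {
  # S(60 months): inflammatory & intermediate > fibrotic > necrotic
  ok <- 0; seeds <- 1:20
  for (seed in seeds) {
    co <- generate_cohort(cohort_config(n = 400), seed = seed)
    km <- km_estimate(co$os_time, co$os_event, co$stromal_type)
    s60 <- vapply(levels(co$stromal_type), function(g) {
      d <- km[km$group == g & km$time <= 60, ]
      if (nrow(d) == 0) 1 else min(d$survival)
    }, numeric(1))
    ok <- ok + (s60["inflammatory"] > s60["fibrotic"] &&
                s60["intermediate"] > s60["fibrotic"] &&
                s60["fibrotic"] > s60["necrotic"])
  }
  expect_gte(ok / length(seeds), 0.95)
})

test_that("fixture suite writes every CSV and the worked example round-trips", {
  dir <- tempfile("fixtures")
  files <- generate_fixture_suite(dir)
  expect_true(all(file.exists(files)))
  expect_setequal(basename(files),
                  c("nacit_slides.csv", "response_marginals.csv",
                    "table1_contingency.csv", "recist_counts.csv",
                    "pdl1_counts.csv", "toy_survival.csv"))
  nacit <- read.csv(file.path(dir, "nacit_slides.csv"))
  g <- classify_pathological_response(nacit$viable_pct)
  expect_equal(as.integer(table(g)), c(1L, 4L, 1L, 1L))
})
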