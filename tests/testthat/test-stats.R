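# Yield tables against a naive tabulator; chi-squared and t-tests against
# closed forms.

test_that("chi-squared matches the closed-form Pearson statistic", {
  expect_equal(chi_squared_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_squared_2x2(10, 10, 10, 10)$p_value, 1)

  # independent closed form: sum((O-E)^2/E)
  pearson <- function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  r <- chi_squared_2x2(20, 80, 40, 60)
  expect_equal(r$statistic, pearson(20, 80, 40, 60), tolerance = 1e-12)
  expect_equal(r$statistic, 9.5238095, tolerance = 1e-6)
  expect_equal(r$df, 1)
  expect_lt(r$p_value, 0.005)
  expect_equal(chi_squared_2x2(1, 0, 0, 1)$statistic, 2)
  # the published European vs Middle-Eastern suspicious-VUS comparison
  r2 <- chi_squared_2x2(41, 362, 8, 35)
  expect_equal(r2$statistic, pearson(41, 362, 8, 35), tolerance = 1e-12)

  # symmetry under row and column swaps
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:50, 4)
    s0 <- chi_squared_2x2(x[1], x[2], x[3], x[4])$statistic
    expect_equal(chi_squared_2x2(x[3], x[4], x[1], x[2])$statistic, s0)
    expect_equal(chi_squared_2x2(x[2], x[1], x[4], x[3])$statistic, s0)
  }
  expect_error(chi_squared_2x2(0, 0, 5, 5), "marginal")
  expect_error(chi_squared_2x2(-1, 2, 3, 4), "non-negative")
  expect_gt(chi_squared_2x2(1, 0, 0, 1)$statistic,
            chi_squared_2x2(1, 0, 0, 1, TRUE)$statistic)
})

test_that("t-tests match hand computation and the summary route agrees", {
  r <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand computation: means 2 and 5, pooled var 1, t = -3/sqrt(2/3)
  r <- t_test_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)

  # summary entry point reproduces the raw-data result exactly
  set.seed(9)
  xs <- rnorm(14, 10, 3); ys <- rnorm(9, 8, 2)
  raw <- t_test_two_sample(xs, ys)
  summ <- t_test_from_summary(length(xs), mean(xs), sd(xs),
                              length(ys), mean(ys), sd(ys))
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(summ$p_value, raw$p_value, tolerance = 1e-12)

  # the published era comparison is significant from summaries alone
  era <- t_test_from_summary(16, 11.9, 5.7, 30, 2.7, 5.4)
  expect_lt(era$p_value, 0.01)

  expect_error(t_test_two_sample(1, c(1, 2)), "n >= 2")
  expect_error(t_test_from_summary(1, 0, 1, 5, 0, 1), "n >= 2")
})

test_that("yield tables equal naive group-by tabulation on a random cohort", {
  sim <- simulate_cohort(sim_config(n_probands = 800, seed = 31))
  adj <- run_cohort_pipeline(sim$probands, sim$variants)

  ys <- yield_by_score(adj)
  ref <- naive_yield(adj, adj$score_bucket)
  tot <- ys[ys$certainty == "total" & ys$stratum != "all", ]
  expect_equal(tot$n, ref$n[match(tot$stratum, ref$stratum)])
  expect_equal(tot$n_LPP, ref$n_LPP[match(tot$stratum, ref$stratum)])
  expect_equal(tot$n_suspicious_VUS,
               ref$n_suspicious_VUS[match(tot$stratum, ref$stratum)])
  # percentages recompute from counts under the declared rounding
  expect_equal(tot$pct_LPP,
               sign(tot$n_LPP) * floor(abs(100 * tot$n_LPP / tot$n) + 0.5))

  ya <- yield_by_ancestry(adj)$table
  refa <- naive_yield(adj[adj$ancestry != "Unknown", ],
                      adj$ancestry[adj$ancestry != "Unknown"])
  expect_equal(ya$n[match(refa$stratum, ya$stratum)], refa$n)
  expect_equal(ya$n_LPP[match(refa$stratum, ya$stratum)], refa$n_LPP)

  # feature-combination strata cover exactly the >=1-feature probands
  yf <- yield_by_feature_combination(adj)
  expect_equal(sum(yf$n), sum(adj$score_total > 0))
})

test_that("degenerate strata render as empty, not as errors", {
  p <- make_probands(2, age = c(25, 45))
  v <- make_variants("T001", consequence = "frameshift",
                     criteria = "PVS1;PM2")
  adj <- run_cohort_pipeline(p, v, test_registry())
  ys <- yield_by_score(adj)
  empty <- ys[ys$certainty == "total" & ys$stratum == "s4plus", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$pct_LPP))
  w <- capture_warnings(ya0 <- yield_by_ancestry(adj))
  expect_true(any(grepl("skipped", w)))
  # identical groups: chi-squared 0, p = 1
  p2 <- make_probands(40, ancestry = rep(c("European", "EastAsian"), 20))
  v2 <- make_variants(p2$proband_id[1:10])
  adj2 <- run_cohort_pipeline(p2, v2, test_registry())
  tests <- suppressWarnings(yield_by_ancestry(adj2)$tests)
  expect_equal(tests$EastAsian$statistic, 0)
  expect_equal(tests$EastAsian$p_value, 1)
})

test_that("render_report writes deterministic artefacts", {
  sim <- simulate_cohort(sim_config(n_probands = 300, seed = 8))
  adj <- run_cohort_pipeline(sim$probands, sim$variants)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressWarnings({render_report(adj, d1); render_report(adj, d2)})
  files <- c("yield_by_score.tsv", "yield_by_feature.tsv",
             "yield_by_ancestry.tsv", "flow_counts.json", "tests.json",
             "report_meta.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
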