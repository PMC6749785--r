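test_that("adaptive quadrature matches the brute-force grid oracle", {
  for (n in c(5L, 26L, 100L)) {
    for (t in c(0, 0.5, 1, 2, 3, 5, 8)) {
      bf <- bf_jzs_t(t, n)
      oracle <- oracle_bf_grid(t, n)
      expect_equal(bf, oracle, tolerance = 5e-4)
    }
  }
})

test_that("the point null beats the diffuse alternative at t = 0", {
  for (n in c(3L, 5L, 26L, 100L)) expect_lt(bf_jzs_t(0, n), 1)
})

test_that("BF10 increases with |t| at fixed n and prior scale", {
  ts <- seq(0, 8, by = 0.5)
  bfs <- vapply(ts, bf_jzs_t, numeric(1), n = 26L)
  expect_true(all(diff(bfs) > 0))
})

test_that("a larger study with proportionally larger t is more evidential", {
  # fixed sample mean and s.d.: t grows as sqrt(n)
  expect_gt(bf_jzs_t(3 * sqrt(2), 40L), bf_jzs_t(3, 20L))
})

test_that("paired BF depends on the data only through t and n", {
  x <- withr::with_seed(1, rnorm(26, 0.15, 0.05))
  y <- withr::with_seed(2, rnorm(26, 0.10, 0.05))
  b1 <- jzs_bf_paired(x, y)
  b2 <- jzs_bf_paired(100 + 7 * x, 100 + 7 * y) # affine rescaling
  expect_equal(b1$bf10, b2$bf10, tolerance = 1e-9)
  # and the paired path agrees with the grid oracle on a fixed dataset
  d <- withr::with_seed(1, rnorm(26, 0.8 * 0.05, 0.05)) # effect d = 0.8
  res <- jzs_bf_one_sample(d)
  expect_equal(res$bf10, oracle_bf_grid(res$t_stat, 26L), tolerance = 5e-4)
})

test_that("one-sided and degenerate paths behave", {
  x <- withr::with_seed(3, rnorm(26, 1.12, 0.05))
  two <- jzs_bf_one_sample(x, mu0 = 1)
  one <- jzs_bf_one_sample(x, mu0 = 1, one_sided = TRUE)
  expect_gt(one$bf10, two$bf10) # evidence concentrates in the correct tail
  expect_error(jzs_bf_one_sample(rep(1, 20), mu0 = 1), "degenerate")
  expect_error(jzs_bf_paired(1:5, 1:4), "paired")
  identical_diffs <- rep(1.1, 20)
  expect_error(jzs_bf_paired(identical_diffs, identical_diffs), "degenerate")
})

test_that("null-supporting data yields BF10 below 1", {
  x <- withr::with_seed(4, rnorm(20, 0, 1))
  y <- x # all paired differences zero would be degenerate; jitter the pairs
  y <- y + withr::with_seed(5, rnorm(20, 0, 1e-3))
  res <- jzs_bf_paired(x, y)
  expect_lt(res$bf10, 1)
})

test_that("evidence classification reproduces the standard bands", {
  expect_equal(classify_evidence(21.375), "strong (H1)")
  expect_equal(classify_evidence(181.107), "extreme (H1)")
  expect_equal(classify_evidence(86.509), "very strong (H1)")
  expect_equal(classify_evidence(1), "no evidence")
  expect_equal(classify_evidence(2), "anecdotal (H1)")
  expect_equal(classify_evidence(3), "anecdotal (H1)")
  expect_equal(classify_evidence(10.0001), "strong (H1)")
  expect_equal(classify_evidence(1 / 50), "very strong (H0)")
  expect_equal(classify_evidence(0.005), "extreme (H0)")
  expect_error(classify_evidence(0), "> 0")
})

test_that("bootstrap group summary is deterministic with sane intervals", {
  th <- tidyr::expand_grid(participant = sprintf("P%02d", 1:26),
                           condition = c("a.leafy", "b.leafy"))
  th$threshold <- withr::with_seed(6, rnorm(nrow(th), 1.15, 0.05))
  g1 <- bootstrap_group_ci(th, resamples = 1500L, seed = 9L)
  g2 <- bootstrap_group_ci(th, resamples = 1500L, seed = 9L)
  expect_identical(g1, g2)
  expect_true(all(g1$ci_lo <= g1$mean & g1$mean <= g1$ci_hi))
  th0 <- th; th0$threshold <- 1.2 # constant column
  g0 <- bootstrap_group_ci(th0, resamples = 1000L, seed = 1L)
  expect_true(all(g0$ci_lo == 1.2 & g0$ci_hi == 1.2 & g0$mean == 1.2))
  expect_error(bootstrap_group_ci(th[1:4, ], resamples = 1000L), ">= 5")
  expect_error(bootstrap_group_ci(th, resamples = 10L), "1000")
})

test_that("bootstrap intervals cover the true mean at near-nominal rate", {
  hits <- vapply(1:200, function(rep) {
    th <- tibble::tibble(participant = sprintf("P%02d", 1:26),
                         condition = "c.leafy",
                         threshold = withr::with_seed(1000 + rep,
                                                      rnorm(26, 0, 1)))
    ci <- bootstrap_group_ci(th, resamples = 1000L, seed = rep)
    ci$ci_lo <= 0 && 0 <= ci$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("bayes_compare assembles the full comparison table", {
  co <- generate_cohort(cohort_spec(n_observers = 12L), seed = 10L)
  th <- tibble::tibble(participant = co$participant,
                       condition = co$condition,
                       threshold = 1 + co$true_threshold)
  out <- bayes_compare(th)
  # 3 pairwise per background + 6 baseline tests
  expect_equal(sum(out$type == "paired"), 6L)
  expect_equal(sum(out$type == "one-sample"), 6L)
  expect_true(all(out$bf10 > 0))
  expect_identical(out$evidence, classify_evidence(out$bf10))
  # all true thresholds exceed baseline by construction: extreme evidence
  base <- out[out$type == "one-sample", ]
  expect_true(all(base$bf10 > 100))
})
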