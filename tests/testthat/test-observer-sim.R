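test_that("the psychometric generator hits its anchor points", {
  obs <- observer_model(0.15, slope = 25, lapse = 0)
  expect_equal(p_correct(obs, 0), 0.5)
  expect_equal(p_correct(obs, 0.15), 0.75)
  obs2 <- observer_model(0.15, slope = 25, lapse = 0.02)
  expect_equal(p_correct(obs2, 5), 0.98, tolerance = 1e-6)
  grid <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(p_correct(obs2, grid)) >= 0))
})

test_that("observer model validation", {
  expect_error(observer_model(-0.1), "thresholds")
  expect_error(observer_model(0.1, slope = 0), "slope")
  expect_error(observer_model(0.1, lapse = 0.5), "lapse")
})

test_that("simulated responses match the generating probabilities", {
  obs <- observer_model(0.12, slope = 20, lapse = 0.02)
  for (delta in c(0.05, 0.12, 0.3)) {
    p_true <- p_correct(obs, delta)
    n <- 10000L
    hits <- withr::with_seed(41, {
      sum(vapply(seq_len(n), function(i) {
        respond(obs, 1 + delta, 1, target_side = "left")$correct
      }, logical(1)))
    })
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(hits / n - p_true), 3 * se)
  }
})

test_that("responses choose the objectively wigglier side when correct", {
  obs <- observer_model(0.1, slope = 1000, lapse = 0)
  # huge slope + large delta: always correct
  r1 <- withr::with_seed(1, respond(obs, 1.5, 1.0, target_side = "left"))
  expect_true(r1$correct); expect_equal(r1$response_side, "left")
  # target smaller than foil: the foil side is the wigglier one
  r2 <- withr::with_seed(1, respond(obs, 0.5, 1.0, target_side = "left"))
  expect_true(r2$correct); expect_equal(r2$response_side, "right")
  expect_error(respond(obs, -1, 1), "> 0")
})

test_that("cohort draws respect the specified distributions", {
  spec0 <- cohort_spec(n_observers = 5L, threshold_sd = 0,
                       slope_sd = 0, lapse_sd = 0)
  c0 <- generate_cohort(spec0, seed = 1L)
  expect_true(all(tapply(c0$true_threshold, c0$condition, sd) == 0))

  spec <- cohort_spec(n_observers = 26L)
  co <- generate_cohort(spec, seed = 2L)
  expect_equal(length(unique(co$participant)), 26L)
  expect_equal(nrow(co), 26L * 6L)
  expect_identical(co, generate_cohort(spec, seed = 2L))

  # Monte-Carlo mean against the truncated-normal closed form
  big <- generate_cohort(cohort_spec(n_observers = 10000L,
                                     threshold_means = c(cond = 0.10)),
                         seed = 3L)
  mu <- truncnorm_mean(0.10, 0.04, 0.005, Inf)
  se <- 0.04 / sqrt(10000)
  expect_lt(abs(mean(big$true_threshold) - mu), 2 * se)
})

test_that("observers materialise from cohort rows", {
  co <- generate_cohort(cohort_spec(n_observers = 3L), seed = 4L)
  obs <- observer_from_cohort(co, "P02")
  row <- co[co$participant == "P02" & co$condition == "ee.leafy", ]
  expect_equal(observer_threshold <- obs$thresholds[["ee.leafy"]],
               row$true_threshold)
  expect_error(observer_from_cohort(co, "P99"), "unknown")
})
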