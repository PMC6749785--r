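test_that("three-down-one-up updates move the unsigned difference", {
  st <- staircase_new(1.2, step = 0.05)
  st <- update_staircase(st, TRUE)
  st <- update_staircase(st, TRUE)
  expect_equal(st$level, 1.2) # two corrects: no move yet
  st <- update_staircase(st, TRUE)
  expect_equal(st$level, 1.15) # third correct steps down
  expect_equal(st$consecutive_correct, 0L)
  st <- update_staircase(st, FALSE)
  expect_equal(st$level, 1.20) # any error steps up
})

test_that("the rule acts on the unsigned difference for the lower staircase", {
  st <- staircase_new(0.8, step = 0.05)
  for (i in 1:3) st <- update_staircase(st, TRUE)
  expect_equal(st$level, 0.85) # difference 0.2 -> 0.15, below baseline
  st <- update_staircase(st, FALSE)
  expect_equal(st$level, 0.80)
})

test_that("step halves at each of the first two reversals, then floors", {
  st <- staircase_new(1.2, step = 0.05, min_step = 0.0125)
  for (i in 1:3) st <- update_staircase(st, TRUE) # down (move 1)
  st <- update_staircase(st, FALSE)               # up: reversal 1
  expect_equal(st$reversals, 1L); expect_equal(st$step, 0.025)
  for (i in 1:3) st <- update_staircase(st, TRUE) # down: reversal 2
  expect_equal(st$reversals, 2L); expect_equal(st$step, 0.0125)
  st <- update_staircase(st, FALSE)               # up: reversal 3
  expect_equal(st$reversals, 3L); expect_equal(st$step, 0.0125)
})

test_that("levels never cross baseline and respect the range clamps", {
  st <- staircase_new(1.2, step = 0.05, min_step = 0.0125, max_trials = 500L)
  for (i in 1:300) st <- update_staircase(st, TRUE)
  expect_gte(st$level, 1 + 0.0125) # clamped just above baseline
  st2 <- staircase_new(1.2, step = 0.05, max_trials = 500L)
  lev <- numeric(200)
  for (i in 1:200) { st2 <- update_staircase(st2, FALSE); lev[i] <- st2$level }
  expect_true(all(diff(lev) >= 0)) # always-wrong: monotone up
  expect_equal(max(lev), 2.5)      # range cap
  st3 <- staircase_new(0.8, step = 0.05, max_trials = 500L)
  for (i in 1:200) st3 <- update_staircase(st3, FALSE)
  expect_equal(st3$level, 0.3)
})

test_that("a terminated staircase refuses further updates", {
  st <- staircase_new(1.2, max_trials = 2L)
  st <- update_staircase(st, TRUE)
  st <- update_staircase(st, FALSE)
  expect_error(update_staircase(st, TRUE), "terminated")
})

test_that("a session yields 360 trials: 30 per staircase, 2 per condition", {
  tr <- run_session(test_observer(), session_design(), seed = 11L)
  expect_equal(nrow(tr), 360L)
  counts <- table(tr$condition, tr$staircase)
  expect_equal(dim(counts), c(6L, 2L))
  expect_true(all(counts == 30L))
  # pedestals come from the nine-step grid and the foil carries it
  expect_true(all(round(tr$pedestal / 0.05) %in% -4:4))
  expect_equal(tr$foil_amp, 1 + tr$pedestal)
  # interleaving preserves per-staircase trial order
  ord <- tapply(tr$trial, paste(tr$condition, tr$staircase),
                function(x) all(diff(x) == 1))
  expect_true(all(ord))
  expect_identical(tr, run_session(test_observer(), session_design(),
                                   seed = 11L))
})

test_that("a long staircase run settles at the transformed up-down
           equilibrium", {
  expect_equal(100 * 0.5^(1 / 3), 79.37005, tolerance = 1e-6)
  obs <- observer_model(0.15, slope = 10, lapse = 0)
  cv <- simulate_staircase_convergence(obs, n_trials = 3e4, seed = 21L)
  expect_equal(cv$percent_correct_at_mean, 79.37, tolerance = 1 / 79.37)
})

test_that("a study stacks per-participant sessions reproducibly", {
  co <- generate_cohort(cohort_spec(n_observers = 3L), seed = 5L)
  tr <- run_study(co, session_design(), seed = 6L)
  expect_equal(nrow(tr), 3L * 360L)
  expect_equal(sort(unique(tr$participant)), c("P01", "P02", "P03"))
  expect_identical(tr, run_study(co, session_design(), seed = 6L))
})
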