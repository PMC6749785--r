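test_that("the fixed-shape logistic passes through 75% at its location", {
  for (a in c(0.05, 0.15, 0.4)) {
    expect_equal(psy_logistic(a, alpha = a, beta = 30), 0.75)
  }
  expect_equal(psy_logistic(0, 0.1, 20), 0.5 + 0.5 / (1 + exp(2)))
})

test_that("least squares recovers exact model data to high precision", {
  for (truth in list(c(0.15, 25), c(0.08, 60), c(0.30, 12))) {
    trials <- exact_psy_trials(truth[1], truth[2])
    f <- fit_psychometric(trials)
    expect_equal(f$alpha, truth[1], tolerance = 1e-6)
    expect_equal(f$beta, truth[2], tolerance = 1e-4)
    expect_lt(f$sse, 1e-10)
    expect_equal(psy_logistic(f$alpha, f$alpha, f$beta), 0.75)
    expect_equal(f$threshold, 1 + f$alpha)
  }
})

test_that("fits are invariant to trial order and staircase provenance", {
  tr <- run_session(test_observer(), session_design(), seed = 31L)
  d <- tr[tr$condition == "ee.leafy", ]
  f1 <- fit_psychometric(d)
  f2 <- fit_psychometric(d[sample.int(nrow(d)), ])
  expect_equal(f1$alpha, f2$alpha)
  expect_equal(f1$beta, f2$beta)
})

test_that("adding correct responses at large differences never raises alpha", {
  tr <- run_session(test_observer(), session_design(), seed = 32L)
  d <- tr[tr$condition == "flat.leafy", ]
  f0 <- fit_psychometric(d)
  extra <- tibble::tibble(target_amp = 1.5, foil_amp = 1, correct = TRUE)
  f1 <- fit_psychometric(dplyr::bind_rows(
    d[, c("target_amp", "foil_amp", "correct")],
    extra[rep(1, 20), ]))
  expect_lte(f1$alpha, f0$alpha + 1e-3) # up to optimiser precision
})

test_that("degenerate all-correct data is flagged at the bound", {
  trials <- tibble::tibble(
    target_amp = rep(1 + c(0.05, 0.1, 0.2, 0.3), each = 10),
    foil_amp = 1, correct = TRUE
  )
  f <- fit_psychometric(trials)
  expect_identical(f$flag, "at_bound")
  expect_warning(threshold_from_fit(f), "flagged")
})

test_that("fit preconditions are enforced", {
  few <- tibble::tibble(target_amp = 1.1, foil_amp = 1, correct = TRUE)
  expect_error(fit_psychometric(few[rep(1, 5), ]), "too few trials")
  one_level <- tibble::tibble(target_amp = rep(1.1, 30), foil_amp = 1,
                              correct = rep(c(TRUE, FALSE), 15))
  expect_error(fit_psychometric(one_level), "levels")
})

test_that("threshold recovery across the staircase pipeline is unbiased", {
  design <- session_design(colourations = "flat", backgrounds = "leafy")
  truth <- 0.15
  rec <- vapply(1:40, function(s) {
    obs <- observer_model(c(flat.leafy = truth), slope = 25, lapse = 0,
                          id = "X")
    tr <- run_session(obs, design, seed = 100 + s)
    fit_psychometric(tr)$alpha
  }, numeric(1))
  expect_lt(abs(median(rec) - truth), 0.03)
})

test_that("tidy, glance and autoplot expose the fit", {
  f <- fit_psychometric(exact_psy_trials(0.15, 25))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta", "gamma", "lambda"))
  expect_true(all(td$fixed == c(FALSE, FALSE, TRUE, TRUE)))
  gl <- glance(f)
  expect_equal(gl$threshold, f$threshold)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("fit_thresholds maps the whole study tidily", {
  co <- generate_cohort(cohort_spec(n_observers = 2L), seed = 7L)
  tr <- run_study(co, session_design(), seed = 8L)
  th <- fit_thresholds(tr)
  expect_equal(nrow(th), 2L * 6L)
  expect_equal(th$threshold, 1 + th$alpha)
  expect_true(all(c("participant", "condition", "colouration", "background",
                    "threshold") %in% names(th)))
})
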