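#' Adaptive staircase state
#'
#' A transformed up-down (3-down-1-up) staircase on the unsigned wiggle
#' difference `|level - 1|`. After three consecutive correct responses the
#' difference shrinks by one step (and the run counter resets); after any
#' incorrect response it grows by one step. The rule equilibrates where the
#' probability of three consecutive corrects equals 1/2, i.e. at
#' `p = 0.5^(1/3) = 79.37%` correct. The step halves at each of the first
#' two reversals down to a minimum step; levels are clamped to
#' `[level_min, level_max]` and never cross baseline 1.0 (the difference is
#' floored at the minimum step), since a crossed staircase would invert the
#' correct-response mapping.
#'
#' @param start_level Starting target amplitude (e.g. 1.2 or 0.8); its side
#'   of baseline fixes the staircase's side.
#' @param step Initial step size in amplitude units (default 0.05).
#' @param min_step Minimum step and minimum baseline distance (0.0125).
#' @param n_down Correct-run length required to step down (default 3).
#' @param max_trials Trials before termination (default 30).
#' @param level_min,level_max Amplitude clamps (0.3, 2.5).
#' @param track_history Keep the per-trial `(level, correct)` history
#'   (default `TRUE`; disable for very long convergence runs).
#' @return A `staircase_state`.
#' @export
staircase_new <- function(start_level, step = 0.05, min_step = 0.0125,
                          n_down = 3L, max_trials = 30L,
                          level_min = 0.3, level_max = 2.5,
                          track_history = TRUE) {
  if (start_level == 1) stop("start_level must differ from baseline 1.0",
                             call. = FALSE)
  if (step <= 0 || min_step <= 0) stop("steps must be > 0", call. = FALSE)
  structure(
    list(level = start_level, side = sign(start_level - 1),
         step = step, min_step = min_step, n_down = as.integer(n_down),
         consecutive_correct = 0L, reversals = 0L, last_move = 0L,
         trial_index = 0L, max_trials = as.integer(max_trials),
         level_min = level_min, level_max = level_max,
         track_history = isTRUE(track_history), history = list()),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> level %.4f (side %+d), trial %d/%d, %d reversals\n",
    x$level, x$side, x$trial_index, x$max_trials, x$reversals))
  invisible(x)
}

staircase_done <- function(state) state$trial_index >= state$max_trials

#' Update a staircase after one response
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @return The updated state.
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (staircase_done(state)) {
    stop("staircase already terminated", call. = FALSE)
  }
  if (state$track_history) {
    state$history[[length(state$history) + 1L]] <-
      list(level = state$level, correct = correct)
  }
  state$trial_index <- state$trial_index + 1L
  delta <- abs(state$level - 1)
  move <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$n_down) {
      delta <- delta - state$step
      state$consecutive_correct <- 0L
      move <- -1L
    }
  } else {
    delta <- delta + state$step
    state$consecutive_correct <- 0L
    move <- 1L
  }
  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversals <- state$reversals + 1L
      if (state$reversals <= 2L) {
        state$step <- max(state$step / 2, state$min_step)
      }
    }
    state$last_move <- move
    delta <- max(delta, state$min_step) # never cross baseline
    level <- 1 + state$side * delta
    state$level <- min(max(level, state$level_min), state$level_max)
  }
  state
}

#' Session design
#'
#' The full within-subject design: every colouration x background condition
#' gets two interleaved staircases (starting above and below baseline), each
#' terminated after `n_trials` trials; on every trial a pedestal offset is
#' added to both amplitudes, drawn uniformly from
#' `seq(-pedestal_max, pedestal_max, by = pedestal_step)`.
#'
#' @param colourations Condition colour labels
#'   (default `c("uniform", "flat", "ee")`).
#' @param backgrounds Background labels (default `c("leafy", "grey")`).
#' @param starts Staircase starting amplitudes (default `c(1.2, 0.8)`).
#' @param n_trials Trials per staircase (default 30).
#' @param pedestal_max,pedestal_step Pedestal grid (0.2, 0.05; nine values).
#' @param step,min_step Staircase step parameters.
#' @return A `session_design`.
#' @export
session_design <- function(colourations = c("uniform", "flat", "ee"),
                           backgrounds = c("leafy", "grey"),
                           starts = c(1.2, 0.8), n_trials = 30L,
                           pedestal_max = 0.2, pedestal_step = 0.05,
                           step = 0.05, min_step = 0.0125) {
  structure(
    list(colourations = colourations, backgrounds = backgrounds,
         starts = starts, n_trials = as.integer(n_trials),
         pedestals = seq(-pedestal_max, pedestal_max, by = pedestal_step),
         step = step, min_step = min_step),
    class = "session_design"
  )
}

#' Run one simulated session
#'
#' Interleaves all staircases of the design by drawing uniformly among the
#' non-terminated ones on every trial; each trial draws a pedestal, builds
#' the target (staircase level + pedestal) and foil (1 + pedestal)
#' amplitudes, assigns the target a random side, queries the observer, and
#' updates the owning staircase. Four independent RNG substreams (staircase
#' selection, pedestals, sides, responses) are derived from the seed so each
#' component is reproducible in isolation.
#'
#' @param observer An [observer_model()] with thresholds for every
#'   `colouration.background` condition of the design.
#' @param design A [session_design()].
#' @param seed Integer seed.
#' @return A tibble of trial records: `participant`, `condition`,
#'   `colouration`, `background`, `staircase`, `trial`, `level`,
#'   `target_amp`, `foil_amp`, `pedestal`, `target_side`, `response_side`,
#'   `correct`.
#' @export
run_session <- function(observer, design = session_design(), seed = 1L) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(design, "session_design"))
  conds <- as.vector(outer(design$colourations, design$backgrounds, paste,
                           sep = "."))
  scs <- list()
  meta <- list()
  for (cc in conds) {
    for (si in seq_along(design$starts)) {
      id <- paste0(cc, "/s", si)
      scs[[id]] <- staircase_new(design$starts[si], step = design$step,
                                 min_step = design$min_step,
                                 max_trials = design$n_trials)
      meta[[id]] <- list(condition = cc, staircase = si)
    }
  }
  n_total <- length(scs) * design$n_trials
  # per-component randomness, each from its own substream, drawn up front
  u_pick <- with_seed(substream_seed(seed, "interleave"),
                      stats::runif(n_total))
  pedestal <- with_seed(substream_seed(seed, "pedestal"),
                        sample(design$pedestals, n_total, replace = TRUE))
  target_side <- with_seed(substream_seed(seed, "sides"),
                           sample(c("left", "right"), n_total,
                                  replace = TRUE))
  u_resp <- with_seed(substream_seed(seed, "responses"),
                      stats::runif(n_total))

  ids <- names(scs)
  done <- stats::setNames(integer(length(scs)), ids)
  cond_of <- vapply(meta, `[[`, "", "condition")
  sc_of <- vapply(meta, function(m) m$staircase, 1L)
  col_of <- vapply(strsplit(cond_of, ".", fixed = TRUE), `[[`, "", 1L)
  bg_of <- vapply(strsplit(cond_of, ".", fixed = TRUE), `[[`, "", 2L)

  out <- list(
    participant = rep(observer$id, n_total), condition = character(n_total),
    colouration = character(n_total), background = character(n_total),
    staircase = integer(n_total), trial = integer(n_total),
    level = numeric(n_total), target_amp = numeric(n_total),
    foil_amp = numeric(n_total), pedestal = pedestal,
    target_side = target_side, response_side = character(n_total),
    correct = logical(n_total)
  )
  for (tr in seq_len(n_total)) {
    open <- ids[done < design$n_trials]
    id <- open[floor(u_pick[tr] * length(open)) + 1L]
    st <- scs[[id]]
    target_amp <- st$level + pedestal[tr]
    foil_amp <- 1 + pedestal[tr]
    ans <- respond(observer, target_amp, foil_amp, condition = cond_of[[id]],
                   target_side = target_side[tr], u = u_resp[tr])
    scs[[id]] <- update_staircase(st, ans$correct)
    done[id] <- done[id] + 1L
    out$condition[tr] <- cond_of[[id]]
    out$colouration[tr] <- col_of[[id]]
    out$background[tr] <- bg_of[[id]]
    out$staircase[tr] <- sc_of[[id]]
    out$trial[tr] <- done[[id]]
    out$level[tr] <- st$level
    out$target_amp[tr] <- target_amp
    out$foil_amp[tr] <- foil_amp
    out$response_side[tr] <- ans$response_side
    out$correct[tr] <- ans$correct
  }
  tibble::as_tibble(out)
}

#' Run a whole simulated study
#'
#' One session per cohort participant, each under its own derived seed.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param design A [session_design()].
#' @param seed Integer master seed.
#' @return A tibble of trial records across participants.
#' @export
run_study <- function(cohort, design = session_design(), seed = 1L) {
  participants <- unique(cohort$participant)
  purrr::map_dfr(participants, function(p) {
    obs <- observer_from_cohort(cohort, p)
    run_session(obs, design, seed = substream_seed(seed, paste0("session/", p)))
  })
}

#' Long-run staircase convergence simulation
#'
#' Runs a single free-running staircase (no trial cap) against a known
#' observer for `n_trials` trials and reports the mean level after burn-in
#' together with the observer's true percent-correct at that mean level —
#' the empirical check that the transformed up-down rule equilibrates at
#' `100 * 0.5^(1/3) = 79.37%`.
#'
#' @param observer An [observer_model()] (single unnamed threshold).
#' @param n_trials Number of trials (default 100000).
#' @param burn_in Trials discarded before averaging (default 1000).
#' @param start_level Starting amplitude (default 1.2).
#' @param step,min_step Step schedule (defaults as in the experiment).
#' @param seed Integer seed.
#' @return A list: `mean_level`, `percent_correct_at_mean`,
#'   `analytic_percent` (= `100 * 0.5^(1/3)`).
#' @export
simulate_staircase_convergence <- function(observer, n_trials = 1e5,
                                           burn_in = 1000,
                                           start_level = 1.2, step = 0.05,
                                           min_step = 0.0125, seed = 1L) {
  stopifnot(inherits(observer, "observer_model"))
  st <- staircase_new(start_level, step = step, min_step = min_step,
                      max_trials = n_trials + 1L, track_history = FALSE)
  levels <- numeric(n_trials)
  with_seed(seed, {
    u <- stats::runif(n_trials)
    for (i in seq_len(n_trials)) {
      levels[i] <- st$level
      pc <- p_correct(observer, abs(st$level - 1))
      st <- update_staircase(st, u[i] < pc)
    }
  })
  mean_level <- mean(levels[(burn_in + 1):n_trials])
  list(
    mean_level = mean_level,
    percent_correct_at_mean =
      100 * p_correct(observer, abs(mean_level - 1)),
    analytic_percent = 100 * 0.5^(1 / 3),
    levels = levels
  )
}
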