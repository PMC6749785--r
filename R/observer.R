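#' Simulated observer model
#'
#' A statistical observer for the 2AFC wiggle task. The probability of a
#' correct response depends only on the folded amplitude difference
#' `delta = |target_amp - foil_amp|` through the logistic
#' `p(delta) = guess + (1 - guess - lapse) / (1 + exp(-slope (delta - thr)))`
#' with guess rate 0.5 (2AFC) and a small lapse rate; the shared pedestal
#' cancels and leaves the observer's decision unchanged, which is the point
#' of a pedestal design.
#'
#' @param thresholds Named numeric vector of true thresholds `delta*`
#'   (amplitude-difference units, > 0), one per condition label, or a single
#'   unnamed value used for every condition.
#' @param slope Logistic rate per amplitude unit (> 0).
#' @param lapse Lapse probability in `[0, 0.06]` (default 0.02).
#' @param id Observer identifier.
#' @return An `observer_model`.
#' @export
observer_model <- function(thresholds, slope = 20, lapse = 0.02, id = "obs") {
  if (any(thresholds <= 0)) stop("thresholds must be > 0", call. = FALSE)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (lapse < 0 || lapse > 0.06) stop("lapse must lie in [0, 0.06]",
                                      call. = FALSE)
  structure(
    list(thresholds = thresholds, slope = slope, lapse = lapse,
         guess = 0.5, id = id),
    class = "observer_model"
  )
}

observer_threshold <- function(obs, condition) {
  thr <- obs$thresholds
  if (is.null(names(thr)) || length(thr) == 1L) return(thr[[1]])
  if (!condition %in% names(thr)) {
    stop("observer has no threshold for condition '", condition, "'",
         call. = FALSE)
  }
  thr[[condition]]
}

#' Probability of a correct response at a given amplitude difference
#'
#' At `delta = 0` the probability is exactly the 2AFC guess rate 0.5; at the
#' observer's threshold with zero lapse it is 0.75; it saturates at
#' `1 - lapse`.
#'
#' @param obs An [observer_model()].
#' @param delta Folded amplitude difference(s), >= 0.
#' @param condition Condition label selecting the observer's threshold.
#' @return Probability/ies of a correct choice.
#' @export
p_correct <- function(obs, delta, condition = NULL) {
  stopifnot(inherits(obs, "observer_model"))
  thr <- observer_threshold(obs, condition)
  p <- obs$guess + (1 - obs$guess - obs$lapse) /
    (1 + exp(-obs$slope * (delta - thr)))
  ifelse(delta == 0, obs$guess, p)
}

#' Simulate one 2AFC response
#'
#' The observer picks the side it perceives as more wiggly: the truly
#' larger-amplitude side with probability `p_correct(|target - foil|)`. When
#' the amplitudes are equal the choice is a coin flip scored against the
#' target side.
#'
#' @param obs An [observer_model()].
#' @param target_amp,foil_amp Amplitudes (> 0).
#' @param condition Condition label.
#' @param target_side `"left"` or `"right"`.
#' @param u Uniform(0,1) variate driving the choice; defaults to a fresh
#'   draw, but callers managing their own RNG substreams may supply it.
#' @return List with `response_side`, `correct` (logical).
#' @export
respond <- function(obs, target_amp, foil_amp, condition = NULL,
                    target_side = "left", u = stats::runif(1)) {
  if (target_amp <= 0 || foil_amp <= 0) stop("amplitudes must be > 0",
                                             call. = FALSE)
  delta <- abs(target_amp - foil_amp)
  p <- p_correct(obs, delta, condition)
  correct <- u < p
  bigger_side <- if (target_amp >= foil_amp) target_side else
    setdiff(c("left", "right"), target_side)
  response_side <- if (correct) bigger_side else
    setdiff(c("left", "right"), bigger_side)
  list(response_side = response_side, correct = correct)
}

#' Cohort specification for the synthetic study
#'
#' Defines the population the simulated participants are drawn from:
#' per-condition mean true thresholds with between-observer spread, a slope
#' distribution, and a lapse distribution. The default means order the
#' conditions as edge-enhanced > flat disruptive > uniform on both
#' backgrounds — the qualitative pattern the pipeline is designed to detect;
#' the magnitudes are package defaults, not measured values.
#'
#' @param n_observers Number of observers (default 26).
#' @param threshold_means Named numeric vector of per-condition mean true
#'   thresholds (amplitude-difference units).
#' @param threshold_sd Between-observer s.d. of thresholds (default 0.04).
#' @param slope_mean,slope_sd Slope distribution (Normal, truncated > 2).
#' @param lapse_mean,lapse_sd Lapse distribution (Normal, truncated to
#'   `[0, 0.06]`).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_observers = 26L,
                        threshold_means = c(
                          "uniform.leafy" = 0.10, "flat.leafy" = 0.12,
                          "ee.leafy" = 0.20, "uniform.grey" = 0.09,
                          "flat.grey" = 0.10, "ee.grey" = 0.15),
                        threshold_sd = 0.04,
                        slope_mean = 20, slope_sd = 4,
                        lapse_mean = 0.02, lapse_sd = 0.01) {
  n_observers <- as.integer(n_observers)
  if (is.na(n_observers) || n_observers < 2L) {
    stop("n_observers must be >= 2", call. = FALSE)
  }
  if (threshold_sd < 0 || slope_sd < 0 || lapse_sd < 0) {
    stop("all s.d. must be >= 0", call. = FALSE)
  }
  if (is.null(names(threshold_means))) {
    stop("threshold_means must be a named vector of conditions",
         call. = FALSE)
  }
  structure(
    list(n_observers = n_observers, threshold_means = threshold_means,
         threshold_sd = threshold_sd, slope_mean = slope_mean,
         slope_sd = slope_sd, lapse_mean = lapse_mean, lapse_sd = lapse_sd),
    class = "cohort_spec"
  )
}

#' Draw a cohort of simulated observers
#'
#' Thresholds are Normal around the per-condition means, truncated positive
#' (floor 0.005); slopes Normal truncated above 2; lapses Normal truncated to
#' `[0, 0.06]`. Deterministic under the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per observer x condition: `participant`,
#'   `condition`, `true_threshold`, `slope`, `lapse`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_observers
  conds <- names(spec$threshold_means)
  with_seed(seed, {
    slopes <- rnorm_trunc(n, spec$slope_mean, spec$slope_sd, 2, Inf)
    lapses <- rnorm_trunc(n, spec$lapse_mean, spec$lapse_sd, 0, 0.06)
    thr <- vapply(conds, function(cc) {
      rnorm_trunc(n, spec$threshold_means[[cc]], spec$threshold_sd,
                  0.005, Inf)
    }, numeric(n))
    if (n == 1L) thr <- matrix(thr, nrow = 1L)
    tibble::tibble(
      participant = rep(sprintf("P%02d", seq_len(n)), times = length(conds)),
      condition = rep(conds, each = n),
      true_threshold = as.vector(thr),
      slope = rep(slopes, times = length(conds)),
      lapse = rep(lapses, times = length(conds))
    )
  })
}

#' Materialise one observer from a cohort table
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param participant Participant id.
#' @return An [observer_model()].
#' @export
observer_from_cohort <- function(cohort, participant) {
  rows <- cohort[cohort$participant == participant, ]
  if (nrow(rows) == 0L) stop("unknown participant", call. = FALSE)
  thr <- stats::setNames(rows$true_threshold, rows$condition)
  observer_model(thr, slope = rows$slope[1], lapse = rows$lapse[1],
                 id = participant)
}
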