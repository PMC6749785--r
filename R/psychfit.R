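#' Logistic psychometric function for 2AFC wiggle discrimination
#'
#' `psi(delta) = gamma + (1 - gamma - lambda) / (1 + exp(-beta (delta -
#' alpha)))` with guess rate `gamma = 0.5` and lapse `lambda = 0` held
#' fixed, so `psi(alpha) = 0.75` exactly: the location parameter *is* the
#' 75%-correct folded difference.
#'
#' @param delta Folded amplitude difference(s).
#' @param alpha Location (amplitude-difference units).
#' @param beta Rate (per amplitude unit).
#' @param gamma Guess rate (fixed 0.5).
#' @param lambda Lapse rate (fixed 0).
#' @return Probability/ies correct.
#' @export
psy_logistic <- function(delta, alpha, beta, gamma = 0.5, lambda = 0) {
  gamma + (1 - gamma - lambda) / (1 + exp(-beta * (delta - alpha)))
}

#' Fit the psychometric function to one condition's trials
#'
#' Trials are folded to `delta = |target_amp - foil_amp|` (the shared
#' pedestal cancels), the proportion correct is computed per distinct level,
#' and `(alpha, beta)` minimise the trial-count-weighted sum of squared
#' residuals between those proportions and [psy_logistic()], with
#' `gamma = 0.5`, `lambda = 0` fixed and `beta > 0`. Bounded multi-start
#' minimisation (`alpha` in `[0.005, 0.6]`, `beta` in `[1, 200]`) keeps the
#' best of all starts.
#'
#' @param trials Data frame of trial records for a single participant and
#'   condition, with columns `target_amp`, `foil_amp`, `correct`.
#' @param min_trials Minimum number of trials (default 20).
#' @param min_levels Minimum number of distinct folded levels (default 3).
#' @return A `psychometric_fit`: `alpha`, `beta`, `gamma`, `lambda`,
#'   `threshold` (= `1 + alpha`), `sse`, `n_trials`, `n_levels`, `flag`
#'   (`"ok"`, or `"at_bound"` when alpha pinned to a box edge), and the
#'   per-level summary tibble `levels`.
#' @export
fit_psychometric <- function(trials, min_trials = 20L, min_levels = 3L) {
  stopifnot(all(c("target_amp", "foil_amp", "correct") %in% names(trials)))
  if (nrow(trials) < min_trials) {
    stop("too few trials to fit (need >= ", min_trials, ")", call. = FALSE)
  }
  delta <- round(abs(trials$target_amp - trials$foil_amp), 10)
  corr <- as.numeric(trials$correct)
  key <- factor(delta)
  n_lv <- as.numeric(rowsum(rep(1, length(delta)), key))
  p_lv <- as.numeric(rowsum(corr, key)) / n_lv
  d_lv <- as.numeric(levels(key))
  lv <- tibble::tibble(delta = d_lv, n = n_lv, p = p_lv)
  if (nrow(lv) < min_levels) {
    stop("too few distinct folded levels to fit (need >= ", min_levels, ")",
         call. = FALSE)
  }
  sse <- function(par) {
    sum(n_lv * (p_lv - psy_logistic(d_lv, par[1], par[2]))^2)
  }
  lower <- c(0.005, 1); upper <- c(0.6, 200)
  # data-driven alpha start: the level whose observed p is nearest 0.75
  a0 <- d_lv[which.min(abs(p_lv - 0.75))]
  starts <- rbind(
    expand.grid(alpha = c(0.05, 0.15, 0.35), beta = c(10, 40, 120)),
    data.frame(alpha = min(max(a0, lower[1]), upper[1]), beta = 30)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  alpha <- best$par[1]; beta <- best$par[2]
  flag <- if (alpha <= lower[1] + 1e-9 || alpha >= upper[1] - 1e-9)
    "at_bound" else "ok"
  structure(
    list(alpha = alpha, beta = beta, gamma = 0.5, lambda = 0,
         threshold = 1 + alpha, sse = best$value,
         n_trials = nrow(trials), n_levels = nrow(lv), flag = flag,
         levels = lv),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> alpha %.4f, beta %.2f, threshold %.4f (%s)\n",
    x$alpha, x$beta, x$threshold, x$flag))
  invisible(x)
}

#' 75%-correct wiggle threshold from a fit
#'
#' The target amplitude whose folded difference sits at the 75% point:
#' `1 + alpha`. A fit flagged degenerate propagates its flag as a warning.
#'
#' @param fit A `psychometric_fit`.
#' @return Amplitude multiplier (> 1 for any positive alpha).
#' @export
threshold_from_fit <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (fit$flag != "ok") {
    warning("threshold taken from a flagged fit (", fit$flag, ")",
            call. = FALSE)
  }
  1 + fit$alpha
}

#' Fit thresholds for every participant x condition
#'
#' @param trials Trial-record tibble (e.g. from [run_study()]).
#' @return A tibble: `participant`, `condition`, `colouration`,
#'   `background`, `alpha`, `beta`, `threshold`, `sse`, `flag`.
#' @export
fit_thresholds <- function(trials) {
  stopifnot(all(c("participant", "condition") %in% names(trials)))
  grp <- dplyr::group_by(trials, .data$participant, .data$condition)
  out <- dplyr::group_modify(grp, function(d, key) {
    f <- fit_psychometric(d)
    tibble::tibble(
      colouration = d$colouration[1], background = d$background[1],
      alpha = f$alpha, beta = f$beta, threshold = f$threshold,
      sse = f$sse, flag = f$flag
    )
  })
  dplyr::ungroup(out)
}

#' @rdname fit_psychometric
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lambda),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, sse = x$sse,
                 n_trials = x$n_trials, n_levels = x$n_levels,
                 flag = x$flag)
}

#' Plot a psychometric fit
#'
#' Observed proportion correct per folded level (point size = trials) with
#' the fitted logistic and the 75% threshold marked.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(
    delta = seq(0, max(object$levels$delta) * 1.1, length.out = 200)
  )
  grid$p <- psy_logistic(grid$delta, object$alpha, object$beta)
  ggplot2::ggplot(object$levels, ggplot2::aes(x = .data$delta, y = .data$p)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 3) +
    ggplot2::labs(x = "folded amplitude difference", y = "P(correct)",
                  size = "trials") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::theme_minimal()
}
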