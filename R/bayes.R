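#' Default-prior (JZS) Bayes factor from a t statistic
#'
#' Computes `BF10` for a one-sample (or paired-difference) t test under the
#' default Jeffreys-Zellner-Siow setup: a point null against an alternative
#' that places a Cauchy(0, r) prior on the standardised effect size.
#' Marginalising the effect gives the g-prior integral
#' `BF10 = [int_0^inf (1 + N g r^2)^(-1/2)
#'   (1 + t^2 / ((1 + N g r^2) nu))^(-(nu+1)/2) pi(g) dg] /
#'   (1 + t^2/nu)^(-(nu+1)/2)`
#' with `pi(g)` the inverse-gamma(1/2, 1/2) density and `nu = n - 1`,
#' evaluated by adaptive quadrature (relative tolerance 1e-8). The one-sided
#' variant (effect > 0) integrates the equivalent noncentral-t formulation
#' over a half-Cauchy prior.
#'
#' @param t t statistic.
#' @param n Sample size (number of differences), >= 3.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param one_sided If `TRUE`, the alternative is restricted to positive
#'   effects.
#' @return `BF10` (positive scalar).
#' @export
bf_jzs_t <- function(t, n, r = sqrt(2) / 2, one_sided = FALSE) {
  stopifnot(is.finite(t), n >= 3, r > 0)
  nu <- n - 1
  if (!one_sided) {
    integrand <- function(g) {
      a <- 1 + n * g * r^2
      a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
        (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
    }
    num <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                            abs.tol = 0)$value
    den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    return(num / den)
  }
  # one-sided: marginal likelihood under a half-Cauchy(0, r) prior on the
  # standardised effect delta, via the noncentral-t likelihood of t
  m1 <- stats::integrate(function(delta) {
    # dt() warns about reduced precision at extreme noncentrality; the
    # quadrature tolerance dominates any such loss
    suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n))) *
      2 * stats::dcauchy(delta, 0, r)
  }, 0, Inf, rel.tol = 1e-8, abs.tol = 0)$value
  m0 <- stats::dt(t, nu)
  m1 / m0
}

new_bayes_result <- function(comparison, t, n, bf10, r, direction) {
  structure(
    list(comparison = comparison, t_stat = t, n = n, bf10 = bf10,
         prior_scale = r, direction = direction,
         evidence_label = classify_evidence(bf10)),
    class = "bayes_result"
  )
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("<bayes_result> %s: t(%d) = %.3f, BF10 = %.3f (%s)\n",
              x$comparison, x$n - 1L, x$t_stat, x$bf10, x$evidence_label))
  invisible(x)
}

#' Paired-samples JZS Bayes factor
#'
#' Within-subjects Bayesian t test on the per-participant differences
#' `x - y`.
#'
#' @param x,y Numeric vectors of per-participant thresholds, paired by
#'   position; equal lengths, n >= 3.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param one_sided Restrict the alternative to positive mean difference.
#' @param comparison Label carried into the result.
#' @return A `bayes_result`.
#' @export
jzs_bf_paired <- function(x, y, r = sqrt(2) / 2, one_sided = FALSE,
                          comparison = "x - y") {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)",
                                   call. = FALSE)
  jzs_bf_one_sample(x - y, mu0 = 0, r = r, one_sided = one_sided,
                    comparison = comparison)
}

#' One-sample JZS Bayes factor against a baseline
#'
#' @param x Numeric vector of thresholds, n >= 3.
#' @param mu0 Null value (e.g. the baseline wiggle amplitude 1.0).
#' @param r Cauchy prior scale.
#' @param one_sided Restrict the alternative to `mean > mu0`.
#' @param comparison Label carried into the result.
#' @return A `bayes_result`.
#' @export
jzs_bf_one_sample <- function(x, mu0 = 0, r = sqrt(2) / 2,
                              one_sided = FALSE, comparison = "x - mu0") {
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  d <- x - mu0
  s <- stats::sd(d)
  if (s < 1e-12) stop("degenerate data: zero-variance differences",
                      call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  bf <- bf_jzs_t(t, n, r = r, one_sided = one_sided)
  new_bayes_result(comparison, t, n, bf, r,
                   if (one_sided) "one-sided" else "two-sided")
}

#' Classify Bayes-factor evidence strength
#'
#' Standard category bounds: `BF10` in (1,3] anecdotal, (3,10] moderate,
#' (10,30] strong, (30,100] very strong, above 100 extreme — evidence for
#' H1; the mirrored reciprocal bands label evidence for H0; `BF10 = 1` is
#' "no evidence".
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character label(s).
#' @export
classify_evidence <- function(bf10) {
  if (any(bf10 <= 0)) stop("bf10 must be > 0", call. = FALSE)
  one <- function(b) {
    if (b == 1) return("no evidence")
    hyp <- if (b > 1) "H1" else "H0"
    v <- if (b > 1) b else 1 / b
    band <- if (v <= 3) "anecdotal" else if (v <= 10) "moderate" else
      if (v <= 30) "strong" else if (v <= 100) "very strong" else "extreme"
    paste0(band, " (", hyp, ")")
  }
  vapply(bf10, one, character(1))
}

#' Pairwise and baseline Bayes-factor analysis of a threshold table
#'
#' Runs within-subjects JZS t tests between every requested condition pair
#' and one-sample tests of each condition against the baseline amplitude.
#'
#' @param thresholds Tibble from [fit_thresholds()] (`participant`,
#'   `condition`, `threshold`).
#' @param comparisons List of length-2 character vectors of condition
#'   labels to compare pairwise; `NULL` compares all pairs sharing a
#'   background.
#' @param baseline Null value for the one-sample tests (default 1.0);
#'   `NULL` skips them.
#' @param r Cauchy prior scale.
#' @param one_sided_baseline Use a one-sided alternative (threshold >
#'   baseline) for the baseline tests.
#' @return A tibble: `comparison`, `type`, `t_stat`, `n`, `bf10`,
#'   `evidence`.
#' @export
bayes_compare <- function(thresholds, comparisons = NULL, baseline = 1.0,
                          r = sqrt(2) / 2, one_sided_baseline = FALSE) {
  wide <- tidyr::pivot_wider(
    thresholds[, c("participant", "condition", "threshold")],
    names_from = "condition", values_from = "threshold"
  )
  conds <- setdiff(names(wide), "participant")
  if (is.null(comparisons)) {
    bgs <- unique(sub("^.*\\.", "", conds))
    comparisons <- list()
    for (bg in bgs) {
      cc <- conds[endsWith(conds, paste0(".", bg))]
      if (length(cc) >= 2) {
        comparisons <- c(comparisons, utils::combn(cc, 2, simplify = FALSE))
      }
    }
  }
  out <- purrr::map_dfr(comparisons, function(pr) {
    res <- jzs_bf_paired(wide[[pr[1]]], wide[[pr[2]]], r = r,
                         comparison = paste(pr[1], "vs", pr[2]))
    tibble::tibble(comparison = res$comparison, type = "paired",
                   t_stat = res$t_stat, n = res$n, bf10 = res$bf10,
                   evidence = res$evidence_label)
  })
  if (!is.null(baseline)) {
    base <- purrr::map_dfr(conds, function(cc) {
      res <- jzs_bf_one_sample(wide[[cc]], mu0 = baseline, r = r,
                               one_sided = one_sided_baseline,
                               comparison = paste(cc, "vs baseline"))
      tibble::tibble(comparison = res$comparison, type = "one-sample",
                     t_stat = res$t_stat, n = res$n, bf10 = res$bf10,
                     evidence = res$evidence_label)
    })
    out <- dplyr::bind_rows(out, base)
  }
  out
}

#' Bootstrap group summary of thresholds
#'
#' Per-condition mean threshold with a percentile bootstrap CI obtained by
#' resampling participants with replacement.
#'
#' @param thresholds Tibble with `participant`, `condition`, `threshold`.
#' @param resamples Bootstrap resamples (default 2000, >= 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A tibble: `condition`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
bootstrap_group_ci <- function(thresholds, resamples = 2000L, conf = 0.95,
                               seed = 1L) {
  wide <- tidyr::pivot_wider(
    thresholds[, c("participant", "condition", "threshold")],
    names_from = "condition", values_from = "threshold"
  )
  n <- nrow(wide)
  if (n < 5L) stop("need >= 5 participants for a bootstrap CI",
                   call. = FALSE)
  if (resamples < 1000L) stop("need >= 1000 resamples", call. = FALSE)
  conds <- setdiff(names(wide), "participant")
  mat <- as.matrix(wide[, conds])
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * resamples, replace = TRUE), resamples, n)
    b <- apply(idx, 1L, function(ii) colMeans(mat[ii, , drop = FALSE]))
    if (is.null(dim(b))) matrix(b, ncol = 1L) else t(b)
  })
  a <- (1 - conf) / 2
  tibble::tibble(
    condition = conds,
    mean = colMeans(mat),
    ci_lo = apply(boots, 2L, stats::quantile, probs = a, names = FALSE),
    ci_hi = apply(boots, 2L, stats::quantile, probs = 1 - a, names = FALSE),
    n = n
  )
}

#' @rdname jzs_bf_one_sample
#' @param x A `bayes_result`.
#' @param ... Unused.
#' @export
tidy.bayes_result <- function(x, ...) {
  tibble::tibble(comparison = x$comparison, t_stat = x$t_stat, n = x$n,
                 bf10 = x$bf10, prior_scale = x$prior_scale,
                 direction = x$direction, evidence = x$evidence_label)
}

#' @rdname jzs_bf_one_sample
#' @export
glance.bayes_result <- function(x, ...) tidy.bayes_result(x)

#' Plot group thresholds with bootstrap CIs
#'
#' @param group Tibble from [bootstrap_group_ci()].
#' @param baseline Reference line (default 1.0).
#' @return A ggplot.
#' @export
plot_group_thresholds <- function(group, baseline = 1.0) {
  g <- tidyr::separate(group, "condition", into = c("colouration",
                                                    "background"),
                       sep = "\\.", fill = "right", remove = FALSE)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$colouration, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = baseline, linetype = 2) +
    ggplot2::facet_wrap(~background) +
    ggplot2::coord_cartesian(
      ylim = c(baseline * 0.95, max(g$ci_hi) * 1.05)) +
    ggplot2::labs(x = NULL, y = "wiggle threshold (amplitude multiple)") +
    ggplot2::theme_minimal()
}
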