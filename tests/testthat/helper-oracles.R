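# Independent oracles used across the suite.

# Brute-force JZS Bayes factor: marginal likelihood of t under a Cauchy(0, r)
# prior on the standardised effect, written as a noncentral-t mixture and
# integrated by the trapezoid rule on the substitution delta = r * tan(theta)
# (so the infinite range maps to (-pi/2, pi/2)). Deliberately a different
# parameterisation and a different integrator from the package's adaptive
# g-prior quadrature.
oracle_bf_grid <- function(t, n, r = sqrt(2) / 2, n_grid = 40001L,
                           one_sided = FALSE) {
  nu <- n - 1
  lo <- if (one_sided) 0 else -pi / 2
  theta <- seq(lo + 1e-9, pi / 2 - 1e-9, length.out = n_grid)
  delta <- r * tan(theta)
  # d delta = r sec^2(theta) d theta; Cauchy density in delta cancels to
  # 1 / (pi r sec^2) so the integrand in theta is dt(t; nu, ncp) / pi
  # dt() flags reduced precision for extreme ncp; harmless at our tolerance
  f <- suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n))) / pi
  if (one_sided) f <- 2 * f
  h <- diff(theta[1:2])
  m1 <- h * (sum(f) - (f[1] + f[length(f)]) / 2)
  m1 / stats::dt(t, nu)
}

# Trials lying exactly on a psychometric curve: for target proportions p
# (multiples of 1/n_per), solve psi(delta) = p for delta so a least-squares
# fit can reach zero residual and must recover (alpha, beta) exactly.
exact_psy_trials <- function(alpha, beta, p_levels = seq(0.55, 0.95, 0.05),
                             n_per = 20L) {
  stopifnot(all(abs(p_levels * n_per - round(p_levels * n_per)) < 1e-9))
  delta <- alpha - log(0.5 / (p_levels - 0.5) - 1) / beta
  rows <- lapply(seq_along(delta), function(i) {
    k <- round(p_levels[i] * n_per)
    tibble::tibble(target_amp = 1 + delta[i], foil_amp = 1,
                   correct = rep(c(TRUE, FALSE), c(k, n_per - k)))
  })
  dplyr::bind_rows(rows)
}

# Mean of a Normal(mean, sd) truncated to [lo, hi] (closed form)
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Grey-ramp colour population whose CIE L values are (approximately) uniform
# on [l_lo, l_hi]; used to make percentile bands analytically predictable.
grey_population <- function(n = 2000L, l_lo = 0, l_hi = 100) {
  l <- seq(l_lo, l_hi, length.out = n)
  rgb <- farver::convert_colour(cbind(l, 0, 0), from = "lab", to = "rgb")
  pmin(pmax(rgb / 255, 0), 1)
}

# Palette with exactly known patch lightness values (neutral greys)
grey_palette <- function(l_a = 40, l_b = 60) {
  srgb <- function(l) {
    as.numeric(pmin(pmax(
      farver::convert_colour(cbind(l, 0, 0), "lab", "rgb") / 255, 0), 1))
  }
  structure(
    list(colour_a = list(srgb = srgb(l_a), L = l_a),
         colour_b = list(srgb = srgb(l_b), L = l_b)),
    class = "patch_palette"
  )
}

# Lightness plane of an sRGB image array
image_L <- function(img) {
  d <- dim(img)
  matrix(farver::convert_colour(matrix(img, ncol = 3) * 255,
                                "rgb", "lab")[, 1], d[1], d[2])
}

# Six-condition observer used by session-level tests
test_observer <- function(id = "P01", slope = 20, lapse = 0.02) {
  observer_model(c(uniform.leafy = 0.10, flat.leafy = 0.12, ee.leafy = 0.18,
                   uniform.grey = 0.09, flat.grey = 0.10, ee.grey = 0.15),
                 slope = slope, lapse = lapse, id = id)
}
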