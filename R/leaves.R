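#' Leaf background specification
#'
#' Parameters of the leafy background: ellipse-like leaves scattered
#' uniformly over a torus-wrapped canvas, drawn back-to-front, each casting a
#' shadow immediately to its left. Leaf heights are log-normally jittered
#' around the mean; a leaf's height parameter is its realised vertical extent
#' (the rotated ellipse is rescaled so this holds exactly, keeping the
#' realised mean height an unbiased match to `mean_height_deg`). Leaf colours
#' are drawn in CIELCh: lightness ~ Normal(l_mean, l_sd) truncated to
#' `l_range`, hue angle ~ Normal(hue_mean, hue_sd) degrees (120 = green),
#' chroma ~ Normal(chroma_mean, chroma_sd) floored at 2 — a naturalistic
#' green/brown population with broad lightness spread.
#'
#' @param n_leaves Number of leaves (default 4096).
#' @param mean_height_deg Mean leaf height, degrees (default 0.68).
#' @param height_jitter Relative s.d. of the log-normal height jitter
#'   (default 0.25).
#' @param shadow_fraction Relative CIE L reduction in shadows (default 0.30).
#' @param aspect Width-to-height ratio of a leaf ellipse (default 1.6:
#'   leaves are wider than tall, so 4096 of them nearly tile the canvas).
#' @param rotation_sd_deg S.d. of leaf rotation about vertical (default 15).
#' @param shadow_shift_deg Leftward displacement of the shadow silhouette
#'   (default 0.15).
#' @param l_mean,l_sd,l_range,hue_mean,hue_sd,chroma_mean,chroma_sd Colour
#'   population parameters (CIELCh).
#' @return A `leaf_spec` object.
#' @export
leaf_spec <- function(n_leaves = 4096L, mean_height_deg = 0.68,
                      height_jitter = 0.25, shadow_fraction = 0.30,
                      aspect = 1.6, rotation_sd_deg = 15,
                      shadow_shift_deg = 0.15,
                      l_mean = 50, l_sd = 12, l_range = c(20, 80),
                      hue_mean = 120, hue_sd = 25,
                      chroma_mean = 30, chroma_sd = 8) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 1L) stop("n_leaves must be >= 1",
                                             call. = FALSE)
  if (mean_height_deg <= 0) stop("mean_height_deg must be > 0", call. = FALSE)
  if (shadow_fraction < 0 || shadow_fraction >= 1) {
    stop("shadow_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_leaves = n_leaves, mean_height_deg = mean_height_deg,
         height_jitter = height_jitter, shadow_fraction = shadow_fraction,
         aspect = aspect, rotation_sd_deg = rotation_sd_deg,
         shadow_shift_deg = shadow_shift_deg,
         l_mean = l_mean, l_sd = l_sd, l_range = l_range,
         hue_mean = hue_mean, hue_sd = hue_sd,
         chroma_mean = chroma_mean, chroma_sd = chroma_sd),
    class = "leaf_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

draw_leaf_colours <- function(n, spec) {
  l <- rnorm_trunc(n, spec$l_mean, spec$l_sd, spec$l_range[1], spec$l_range[2])
  h <- stats::rnorm(n, spec$hue_mean, spec$hue_sd)
  c <- pmax(stats::rnorm(n, spec$chroma_mean, spec$chroma_sd), 2)
  lch_to_srgb(l, c, h)
}

#' Generate a leafy background
#'
#' Scatters `n_leaves` rotated-ellipse leaves uniformly over a torus-wrapped
#' canvas (so coverage has no edge artefacts), draws them in random order,
#' and applies per-leaf shadows. The canvas is first painted with a base
#' colour drawn from the same leaf colour population, so no non-leaf-coloured
#' pixel survives even where no leaf lands; the fraction of pixels painted by
#' an actual leaf is recorded and a coverage note attached when it is low.
#'
#' @param spec A [leaf_spec()].
#' @param cal A `display_calibration`.
#' @param size Canvas side length in pixels (default 1024).
#' @param seed Integer seed; the same seed reproduces the background exactly.
#' @param shadows Apply the shadow pass (default `TRUE`).
#' @return A `leaf_background` with fields `image` (sRGB array), `owner`
#'   (per-pixel index of the topmost leaf, 0 = base layer), `leaf_records`
#'   (tibble: id, centre, height, rotation, colour), `image_unshadowed`,
#'   `shadow_mask`, `coverage` and `spec`.
#' @export
generate_leaf_background <- function(spec = leaf_spec(),
                                     cal = default_calibration(),
                                     size = 1024L, seed = 1L,
                                     shadows = TRUE) {
  stopifnot(inherits(spec, "leaf_spec"), inherits(cal, "display_calibration"))
  size <- as.integer(size)
  n <- spec$n_leaves
  mean_h_px <- deg_to_px(cal, spec$mean_height_deg)
  sdlog <- sqrt(log(1 + spec$height_jitter^2))
  meanlog <- log(mean_h_px) - sdlog^2 / 2 # lognormal mean = mean_h_px

  dat <- with_seed(seed, {
    list(
      cx = stats::runif(n, 0, size), cy = stats::runif(n, 0, size),
      h = stats::rlnorm(n, meanlog, sdlog),
      theta = stats::rnorm(n, 0, spec$rotation_sd_deg) * pi / 180,
      cols = draw_leaf_colours(n, spec),
      base_col = as.numeric(draw_leaf_colours(1L, spec))
    )
  })

  # semi-axes before the vertical-extent rescale
  b0 <- dat$h / 2               # vertical semi-axis
  a0 <- dat$h * spec$aspect / 2 # horizontal semi-axis (leaves wider)
  # vertical extent of the rotated ellipse, then rescale so extent == h
  vext <- 2 * sqrt((a0 * sin(dat$theta))^2 + (b0 * cos(dat$theta))^2)
  k <- dat$h / vext
  a <- a0 * k
  b <- b0 * k

  owner <- matrix(0L, size, size)
  half_w <- a * pmax(abs(cos(dat$theta)), abs(sin(dat$theta))) + b
  for (i in seq_len(n)) {
    # bounding box, generous; indices torus-wrapped
    r <- ceiling(half_w[i]) + 1L
    xs <- floor(dat$cx[i]) + (-r:r)
    ys <- floor(dat$cy[i]) + (-r:r)
    dx <- outer(rep(1, length(ys)), xs + 0.5 - dat$cx[i])
    dy <- outer(ys + 0.5 - dat$cy[i], rep(1, length(xs)))
    u <- (dx * cos(dat$theta[i]) + dy * sin(dat$theta[i])) / a[i]
    v <- (-dx * sin(dat$theta[i]) + dy * cos(dat$theta[i])) / b[i]
    inside <- u * u + v * v <= 1
    if (!any(inside)) next
    yi <- (ys %% size) + 1L
    xi <- (xs %% size) + 1L
    sub <- owner[yi, xi]
    sub[inside] <- i
    owner[yi, xi] <- sub
  }

  img <- array(0, c(size, size, 3L))
  cols <- rbind(dat$base_col, dat$cols) # row 1 = base layer (owner 0)
  for (ch in 1:3) {
    img[, , ch] <- matrix(cols[as.vector(owner) + 1L, ch], size, size)
  }

  records <- tibble::tibble(
    leaf = seq_len(n), cx = dat$cx, cy = dat$cy,
    height_px = dat$h, height_deg = px_to_deg(cal, dat$h),
    rotation_rad = dat$theta,
    r = dat$cols[, 1], g = dat$cols[, 2], b = dat$cols[, 3],
    n_pixels = as.integer(tabulate(owner[owner > 0L], nbins = n))
  )

  bg <- structure(
    list(image = img, image_unshadowed = img, owner = owner,
         leaf_records = records, coverage = mean(owner > 0L),
         shadow_mask = NULL, spec = spec, cal = cal, seed = seed),
    class = "leaf_background"
  )
  if (bg$coverage < 0.95) {
    attr(bg, "coverage_note") <-
      sprintf("only %.1f%% of pixels painted by a leaf; base layer visible",
              100 * bg$coverage)
  }
  if (shadows) bg <- apply_leaf_shadows(bg, spec) else bg
}

#' @export
print.leaf_background <- function(x, ...) {
  cat(sprintf("<leaf_background> %d leaves, %d x %d px, coverage %.1f%%\n",
              nrow(x$leaf_records), nrow(x$owner), ncol(x$owner),
              100 * x$coverage))
  invisible(x)
}

#' Apply leftward leaf shadows
#'
#' Each leaf's silhouette, displaced leftward by `shadow_shift_deg`, darkens
#' whatever surface it falls on — except the leaf itself — by multiplying
#' CIE L by `1 - shadow_fraction` in CIELAB. Shadows are computed from leaf
#' geometry and applied to the unshadowed image, so re-running the pass
#' reproduces the same result rather than compounding.
#'
#' @param bg A `leaf_background`.
#' @param spec A [leaf_spec()]; defaults to the background's own.
#' @return The background with `image` shadowed and `shadow_mask` set.
#' @export
apply_leaf_shadows <- function(bg, spec = bg$spec) {
  stopifnot(inherits(bg, "leaf_background"))
  size <- nrow(bg$owner)
  shift <- max(1L, round(deg_to_px(bg$cal, spec$shadow_shift_deg)))
  # source column for each pixel: the pixel `shift` to its right (torus)
  src_cols <- ((seq_len(size) - 1L + shift) %% size) + 1L
  src_owner <- bg$owner[, src_cols]
  shadow <- src_owner > 0L & src_owner != bg$owner
  bg$shadow_mask <- shadow
  if (spec$shadow_fraction == 0 || !any(shadow)) {
    bg$image <- bg$image_unshadowed
    return(bg)
  }
  lab <- img_to_lab(bg$image_unshadowed)
  lab$L[shadow] <- lab$L[shadow] * (1 - spec$shadow_fraction)
  img <- lab_to_img(lab)
  keep <- !shadow
  for (k in 1:3) {
    layer <- img[, , k]
    layer[keep] <- bg$image_unshadowed[, , k][keep]
    img[, , k] <- layer
  }
  bg$image <- img
  bg
}

#' Colour population of a leaf background
#'
#' All leaf-fill pixel colours (unshadowed), the sample from which disruptive
#' patch palettes are drawn.
#'
#' @param bg A `leaf_background`.
#' @param max_pixels Subsample cap (default 200000) to keep palettes cheap.
#' @param seed Seed for the subsample.
#' @return Matrix of sRGB rows in `[0, 1]`.
#' @export
leaf_colour_population <- function(bg, max_pixels = 2e5, seed = 1L) {
  stopifnot(inherits(bg, "leaf_background"))
  idx <- which(bg$owner > 0L)
  if (length(idx) > max_pixels) {
    idx <- with_seed(seed, sample(idx, max_pixels))
  }
  cbind(bg$image_unshadowed[, , 1][idx],
        bg$image_unshadowed[, , 2][idx],
        bg$image_unshadowed[, , 3][idx])
}
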