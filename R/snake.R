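#' Snake target masks and stimulus scenes
#'
#' The target silhouette is a procedural snake: a constant-thickness tube
#' following a sinusoid `x(t) = A sin(2 pi k t)` down the vertical span, with
#' a rounded head at the top. `A` is calibrated once per geometry so that the
#' amplitude-1.0 silhouette spans exactly the baseline width (82 px: the
#' distance between its leftmost and rightmost occupied columns, 2.44 deg
#' under the default calibration). Other wiggle amplitudes are produced by
#' horizontally resampling the base bitmap, so an amplitude of 0.5 halves and
#' 2.0 doubles the occupied width while the 9.73-deg vertical extent is
#' unchanged.
#'
#' @name snake_stimulus
NULL

snake_cache <- new.env(parent = emptyenv())

# Rasterise the base tube for a given sinusoid amplitude A (px).
raster_snake <- function(A, height_px, r_px, periods, canvas_w) {
  y <- seq_len(height_px) - 0.5
  t <- (y - 0.5) / (height_px - 1)
  xc <- A * sin(2 * pi * periods * t)
  dxdy <- A * 2 * pi * periods * cos(2 * pi * periods * t) / (height_px - 1)
  hw <- r_px * sqrt(1 + dxdy^2) # row half-width of a constant-thickness tube
  cx <- canvas_w / 2
  xs <- matrix(rep(seq_len(canvas_w) - 0.5, each = height_px),
               height_px, canvas_w)
  mask <- abs(xs - (cx + xc)) <= hw
  # rounded head: disc centred on the curve near the top
  head_r <- r_px * 1.35
  hy <- head_r
  ht <- (hy - 0.5) / (height_px - 1)
  hx <- cx + A * sin(2 * pi * periods * ht)
  ys <- matrix(rep(y, canvas_w), height_px, canvas_w)
  mask <- mask | ((xs - hx)^2 + (ys - hy)^2 <= head_r^2)
  mask * 1L
}

mask_extent <- function(mask) {
  occ <- which(colSums(mask) > 0L)
  if (length(occ) == 0L) 0L else max(occ) - min(occ) + 1L
}

# Trim all-empty boundary columns
trim_mask <- function(mask) {
  occ <- which(colSums(mask) > 0L)
  mask[, min(occ):max(occ), drop = FALSE]
}

base_snake <- function(cal, baseline_width_px = 82L, height_deg = 9.73,
                       thickness_deg = 0.45, periods = 2.5) {
  key <- paste(signif(cal$pixel_pitch_mm, 10), cal$distance_mm,
               baseline_width_px, height_deg, thickness_deg, periods,
               sep = "|")
  if (!is.null(snake_cache[[key]])) return(snake_cache[[key]])
  height_px <- round(deg_to_px(cal, height_deg))
  r_px <- deg_to_px(cal, thickness_deg) / 2
  canvas_w <- baseline_width_px * 3L
  f <- function(A) mask_extent(raster_snake(A, height_px, r_px, periods,
                                            canvas_w))
  # extent is a step function of A; bisect for the smallest A giving the
  # target extent, then verify
  lo <- 1; hi <- baseline_width_px
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) >= baseline_width_px) hi <- mid else lo <- mid
  }
  mask <- raster_snake(hi, height_px, r_px, periods, canvas_w)
  if (mask_extent(mask) != baseline_width_px) {
    stop("snake calibration failed to hit the baseline width", call. = FALSE)
  }
  out <- trim_mask(mask)
  snake_cache[[key]] <- out
  out
}

#' Build a snake mask at a given wiggle amplitude
#'
#' @param amplitude Wiggle multiplier in `[0.3, 2.5]`; 1.0 gives the
#'   baseline 82-px width.
#' @param cal A `display_calibration`.
#' @param baseline_width_px Baseline occupied width at amplitude 1 (82).
#' @param height_deg Vertical extent in degrees (9.73).
#' @param thickness_deg Tube thickness in degrees (0.45).
#' @param periods Sinusoid periods over the body (2.5).
#' @return A `snake_mask`: binary matrix `mask` (rows = height, columns =
#'   occupied width), plus `amplitude`, `width_px`, `height_px`.
#' @export
make_snake_mask <- function(amplitude, cal = default_calibration(),
                            baseline_width_px = 82L, height_deg = 9.73,
                            thickness_deg = 0.45, periods = 2.5) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      amplitude < 0.3 || amplitude > 2.5) {
    stop("amplitude must lie in [0.3, 2.5]", call. = FALSE)
  }
  base <- base_snake(cal, baseline_width_px, height_deg, thickness_deg,
                     periods)
  w0 <- ncol(base)
  w <- as.integer(round(amplitude * w0))
  if (w == w0) {
    mask <- base
  } else {
    # row-wise linear interpolation of the bitmap, re-binarised at 0.5;
    # the sub-pixel offset breaks exact half-intensity lattice ties (which
    # would otherwise inflate run lengths by half a pixel per row at
    # rational scale factors)
    src <- (seq_len(w) - 0.5) * w0 / w - 0.5 + 1e-7
    x0 <- seq_len(w0) - 1
    mask <- t(apply(base, 1L, function(row) {
      as.integer(stats::approx(x0, row, xout = src, rule = 2)$y >= 0.5)
    }))
  }
  structure(
    list(mask = mask, amplitude = amplitude, width_px = ncol(mask),
         height_px = nrow(mask), baseline_width_px = as.integer(w0)),
    class = "snake_mask"
  )
}

#' @export
print.snake_mask <- function(x, ...) {
  cat(sprintf("<snake_mask> amplitude %.3f, %d x %d px\n", x$amplitude,
              x$height_px, x$width_px))
  invisible(x)
}

#' Compose a two-snake stimulus scene
#'
#' Samples a camouflage (or uniform) texture through two snake masks — the
#' target at `target_amp`, the foil at `foil_amp` — and places them
#' side-by-side over the background, separated horizontally and with
#' independent random vertical offsets in `[-y_offset_max, +y_offset_max]`
#' degrees so phase alignment carries no cue. The target is assigned a side
#' at random. Each snake samples an independently drawn texture from
#' `textures`.
#'
#' @param target_amp,foil_amp Wiggle amplitudes (multipliers).
#' @param textures List of `camo_texture` objects for this colouration.
#' @param background A `leaf_background`, or `NULL` for the mid-grey field.
#' @param cal A `display_calibration`.
#' @param seed Integer seed.
#' @param size Scene side length in pixels (default 1024).
#' @param separation_deg Centre-to-centre horizontal separation of the two
#'   snakes (default 15.9).
#' @param y_offset_max Maximum vertical offset magnitude, degrees (1.49).
#' @param grey Background grey level for the uniform background, sRGB in
#'   `[0, 1]` (default 0.5, the display's mid-grey).
#' @param snake Optional named list overriding [make_snake_mask()] geometry
#'   (`baseline_width_px`, `height_deg`, `thickness_deg`, `periods`).
#' @return A `stimulus_scene`: `image` plus a one-row `meta` tibble
#'   (amplitudes, sides, offsets, texture indices, seed).
#' @export
compose_scene <- function(target_amp, foil_amp, textures, background = NULL,
                          cal = default_calibration(), seed = 1L,
                          size = 1024L, separation_deg = 15.9,
                          y_offset_max = 1.49, grey = 0.5, snake = list()) {
  size <- as.integer(size)
  draws <- with_seed(seed, list(
    target_left = stats::runif(1) < 0.5,
    y_off = stats::runif(2, -y_offset_max, y_offset_max),
    tex_idx = sample.int(length(textures), 2L, replace = TRUE)
  ))
  mk <- function(a) do.call(make_snake_mask, c(list(a, cal), snake))
  masks <- list(mk(target_amp), mk(foil_amp))
  sides <- if (draws$target_left) c("left", "right") else c("right", "left")

  canvas <- if (is.null(background)) {
    solid_image(rep(grey, 3), size, size)
  } else {
    background$image
  }
  half_sep_px <- deg_to_px(cal, separation_deg) / 2
  centre <- size / 2
  for (i in 1:2) {
    m <- masks[[i]]
    tex <- textures[[draws$tex_idx[i]]]
    x_centre <- centre + if (sides[i] == "left") -half_sep_px else half_sep_px
    y_centre <- centre + deg_to_px(cal, abs(draws$y_off[i])) *
      sign(draws$y_off[i])
    x0 <- round(x_centre - m$width_px / 2)
    y0 <- round(y_centre - m$height_px / 2)
    if (x0 < 0 || y0 < 0 || x0 + m$width_px > size ||
        y0 + m$height_px > size) {
      stop("snake placement exceeds the canvas", call. = FALSE)
    }
    rows <- y0 + seq_len(m$height_px)
    cols <- x0 + seq_len(m$width_px)
    sel <- m$mask == 1L
    for (k in 1:3) {
      patch <- canvas[rows, cols, k]
      texwin <- tex$image[rows, cols, k]
      patch[sel] <- texwin[sel]
      canvas[rows, cols, k] <- patch
    }
  }
  meta <- tibble::tibble(
    target_amp = target_amp, foil_amp = foil_amp,
    target_side = sides[1],
    y_off_target = draws$y_off[1], y_off_foil = draws$y_off[2],
    texture_target = draws$tex_idx[1], texture_foil = draws$tex_idx[2],
    background = if (is.null(background)) "uniform_grey" else "leafy",
    seed = seed
  )
  structure(list(image = canvas, meta = meta), class = "stimulus_scene")
}

#' @export
print.stimulus_scene <- function(x, ...) {
  cat(sprintf("<stimulus_scene> target %.2f (%s) vs foil %.2f on %s\n",
              x$meta$target_amp, x$meta$target_side, x$meta$foil_amp,
              x$meta$background))
  invisible(x)
}
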