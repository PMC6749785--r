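#' Band-pass filter specification
#'
#' Parameters of the radial Gaussian gain applied to white noise in the
#' Fourier domain. The gain at radial frequency `d` (cycles/pixel) is
#' `exp(-(d - mu)^2 / (2 * s^2))`, peaking at 1 when `d == mu`. The Gaussian
#' s.d. is `s = sigma * mu / size` cycles/pixel, i.e. `sigma * mu` is read in
#' cycles per image; read as cycles per pixel the printed parameters would
#' make the gain flat over the whole representable band, so the per-image
#' convention is the one that yields the intended narrow band-pass
#' (peak period ~14 px at the defaults).
#'
#' @param mu Peak radial frequency in cycles/pixel (default 0.07).
#' @param sigma Bandwidth multiplier (dimensionless, default 120).
#' @param size Image side length in pixels (positive even integer).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(mu = 0.07, sigma = 120, size = 1024L) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("mu must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  size <- as.integer(size)
  if (is.na(size) || size <= 0L || size %% 2L != 0L) {
    stop("size must be a positive even integer", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, size = size), class = "filter_spec")
}

# Radial Gaussian gain as a function of frequency d (cycles/pixel)
bandpass_gain <- function(d, spec) {
  s <- spec$sigma * spec$mu / spec$size
  exp(-(d - spec$mu)^2 / (2 * s^2))
}

#' Build the radial band-pass gain field
#'
#' Returns the `size x size` gain matrix in unshifted FFT layout (DC at
#' `[1, 1]`), depending only on radial frequency so the filter is isotropic.
#'
#' @param spec A [filter_spec()].
#' @return Numeric matrix of gains in `[0, 1]`, with attribute `"freq"`
#'   holding the per-axis frequency vector (cycles/pixel).
#' @export
make_bandpass_filter <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- spec$size
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / n # FFT bin frequencies, cycles/pixel
  d <- sqrt(outer(f^2, f^2, `+`))
  g <- bandpass_gain(d, spec)
  attr(g, "freq") <- f
  g
}

#' Pick a two-tone patch palette from a colour population
#'
#' Draws the darker patch colour uniformly from population pixels whose CIE L
#' lies in the 35th-45th percentile band and the lighter one from the
#' 55th-65th band, so the two tones straddle the population median lightness.
#'
#' @param colour_population Numeric matrix, one row per pixel, 3 columns of
#'   sRGB in `[0, 1]` (e.g. from [leaf_colour_population()]).
#' @param seed Integer seed for the draw.
#' @param bands Percentile bands as `c(lo_a, hi_a, lo_b, hi_b)` in
#'   percent; defaults `c(35, 45, 55, 65)`.
#' @return A `patch_palette`: `colour_a` (darker) and `colour_b` (lighter),
#'   each a list with `srgb` (length-3) and `L`.
#' @export
pick_patch_palette <- function(colour_population, seed = 1L,
                               bands = c(35, 45, 55, 65)) {
  stopifnot(is.matrix(colour_population), ncol(colour_population) == 3L)
  if (nrow(colour_population) < 100L) {
    stop("colour population must have >= 100 pixels", call. = FALSE)
  }
  L <- srgb_to_lab(colour_population)[, 1]
  if (diff(range(L)) < 1e-6) {
    stop("degenerate colour population: no brightness spread", call. = FALSE)
  }
  q <- stats::quantile(L, bands / 100, names = FALSE)
  in_a <- which(L >= q[1] & L <= q[2])
  in_b <- which(L >= q[3] & L <= q[4])
  if (length(in_a) == 0L || length(in_b) == 0L) {
    stop("empty percentile band in colour population", call. = FALSE)
  }
  idx <- with_seed(seed, c(sample(in_a, 1L), sample(in_b, 1L)))
  a <- colour_population[idx[1], ]
  b <- colour_population[idx[2], ]
  La <- L[idx[1]]; Lb <- L[idx[2]]
  # percentile bands guarantee La <= Lb; guard against exact ties
  if (La >= Lb) {
    stop("degenerate palette: bands produced non-increasing lightness",
         call. = FALSE)
  }
  structure(
    list(colour_a = list(srgb = a, L = La), colour_b = list(srgb = b, L = Lb)),
    class = "patch_palette"
  )
}

new_camo_texture <- function(image, label_map, colouration, palette = NULL,
                             spec = NULL, seed = NULL, field = NULL,
                             ee = NULL, ee_band = NULL) {
  structure(
    list(image = image, label_map = label_map, colouration = colouration,
         palette = palette, spec = spec, seed = seed, field = field,
         ee = ee, ee_band = ee_band),
    class = "camo_texture"
  )
}

#' @export
print.camo_texture <- function(x, ...) {
  cat(sprintf("<camo_texture> %s, %d x %d px\n", x$colouration,
              nrow(x$label_map), ncol(x$label_map)))
  invisible(x)
}

#' Synthesise a flat disruptive two-tone texture
#'
#' White Gaussian noise is filtered by the radial band-pass gain in the
#' Fourier domain, inverse-transformed, and posterised at the median: pixels
#' strictly above the 50th percentile take the lighter palette colour, the
#' rest (including median ties) the darker one, so each tone covers half the
#' field.
#'
#' @param spec A [filter_spec()].
#' @param palette A `patch_palette`.
#' @param seed Integer seed; the same seed reproduces the texture exactly.
#' @return A `camo_texture` with `colouration = "flat_disruptive"`; the
#'   pre-posterisation field is kept in `$field` for spectral diagnostics.
#' @export
synthesize_two_tone <- function(spec, palette, seed = 1L) {
  stopifnot(inherits(spec, "filter_spec"), inherits(palette, "patch_palette"))
  n <- spec$size
  noise <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  gain <- make_bandpass_filter(spec)
  field <- Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE)) / (n * n)
  if (stats::sd(field) < 1e-12) {
    stop("degenerate texture: filtered field is constant", call. = FALSE)
  }
  med <- stats::median(field)
  label <- (field > med) * 1L # 1 = light patch, 0 = dark patch (ties dark)
  img <- array(0, c(n, n, 3L))
  for (k in 1:3) {
    img[, , k] <- ifelse(label == 1L, palette$colour_b$srgb[k],
                         palette$colour_a$srgb[k])
  }
  new_camo_texture(img, label, "flat_disruptive", palette = palette,
                   spec = spec, seed = seed, field = field)
}

#' Edge-enhancement specification
#'
#' @param total_width_deg Spatial extent of the enhanced band in degrees,
#'   counting both sides of a patch boundary (default 0.63).
#' @param offset_L Lightness change toward the enhanced edge in CIE L units
#'   (default 60): added on the light patch, subtracted on the dark patch.
#' @param profile `"flat"` (a step of full offset across the band) or
#'   `"ramp"` (offset tapering linearly from the boundary to the band edge).
#' @return An `ee_spec` object.
#' @export
ee_spec <- function(total_width_deg = 0.63, offset_L = 60, profile = "flat") {
  if (!is.numeric(total_width_deg) || total_width_deg <= 0) {
    stop("total_width_deg must be > 0", call. = FALSE)
  }
  if (!is.numeric(offset_L) || offset_L < 0) {
    stop("offset_L must be >= 0", call. = FALSE)
  }
  profile <- match.arg(profile, c("flat", "ramp"))
  structure(list(total_width_deg = total_width_deg, offset_L = offset_L,
                 profile = profile),
            class = "ee_spec")
}

#' Apply edge enhancement to a two-tone texture
#'
#' Every pixel whose centre lies within half the total band width of the
#' patch boundary has its CIE L shifted by the offset: up on the light
#' patch, down on the dark patch ("light areas have lighter edges and dark
#' areas have darker edges"). Centre distance is the Euclidean distance
#' transform to the opposite label minus the half-pixel offset between a
#' pixel centre and the boundary plane, the usual rasterisation convention,
#' so a straight boundary's realised band width matches the nominal width
#' to within one pixel. The shifted image is converted back to sRGB with
#' gamut clipping; pixels outside the band are unchanged.
#'
#' @param texture A two-tone `camo_texture`.
#' @param ee An [ee_spec()].
#' @param cal A `display_calibration` used to convert the band width to px.
#' @return A `camo_texture` with `colouration = "edge_enhanced_disruptive"`,
#'   the signed band map in `$ee_band` (+1 light-side band, -1 dark-side),
#'   and the signed pre-clipping CIE L shift in `$ee_dL`.
#' @export
apply_edge_enhancement <- function(texture, ee = ee_spec(),
                                   cal = default_calibration()) {
  stopifnot(inherits(texture, "camo_texture"), inherits(ee, "ee_spec"))
  if (texture$colouration == "uniform") {
    stop("edge enhancement is not applicable to a uniform texture",
         call. = FALSE)
  }
  lab_map <- texture$label_map
  half_px <- deg_to_px(cal, ee$total_width_deg) / 2
  # distance transform to the nearest opposite-label pixel; a pixel centre
  # sits 0.5 px inside that centre-to-centre distance from the boundary
  d_light <- EBImage::distmap(1 * (lab_map == 1L)) # 0 on dark, >0 on light
  d_dark <- EBImage::distmap(1 * (lab_map == 0L))
  band <- matrix(0L, nrow(lab_map), ncol(lab_map))
  band[lab_map == 1L & d_light - 0.5 <= half_px] <- 1L
  band[lab_map == 0L & d_dark - 0.5 <= half_px] <- -1L
  if (ee$offset_L == 0 || !any(band != 0L)) {
    out <- texture
    out$colouration <- "edge_enhanced_disruptive"
    out$ee <- ee
    out$ee_band <- band
    return(out)
  }
  scale <- matrix(1, nrow(band), ncol(band))
  if (ee$profile == "ramp") {
    d <- ifelse(lab_map == 1L, as.numeric(d_light), as.numeric(d_dark))
    scale <- pmax(0, 1 - (d - 1) / half_px) # full offset at the boundary
  }
  lab <- img_to_lab(texture$image)
  dL <- ee$offset_L * scale * band # signed pre-clipping lightness shift
  lab$L <- lab$L + dL
  img <- lab_to_img(lab)
  keep <- band == 0L
  for (k in 1:3) {
    layer <- img[, , k]
    layer[keep] <- texture$image[, , k][keep]
    img[, , k] <- layer
  }
  out <- new_camo_texture(img, lab_map, "edge_enhanced_disruptive",
                          palette = texture$palette, spec = texture$spec,
                          seed = texture$seed, field = texture$field,
                          ee = ee, ee_band = band)
  out$ee_dL <- dL
  out
}

#' Uniform control texture
#'
#' A constant-colour field at the CIELAB midpoint of the two patch colours,
#' so the control matches the mean lightness of the disruptive patterns.
#'
#' @param palette A `patch_palette`.
#' @param size Side length in pixels.
#' @return A `camo_texture` with `colouration = "uniform"`.
#' @export
make_uniform_texture <- function(palette, size = 1024L) {
  stopifnot(inherits(palette, "patch_palette"))
  size <- as.integer(size)
  lab_a <- srgb_to_lab(matrix(palette$colour_a$srgb, 1))
  lab_b <- srgb_to_lab(matrix(palette$colour_b$srgb, 1))
  mid <- lab_to_srgb((lab_a + lab_b) / 2)
  img <- solid_image(as.numeric(mid), size, size)
  new_camo_texture(img, matrix(0L, size, size), "uniform", palette = palette)
}

#' Two-tone texture from an explicit label map
#'
#' Builds a flat disruptive texture directly from a binary patch-label
#' matrix, bypassing noise synthesis. Useful for controlled boundary
#' geometries (e.g. a straight edge for measuring the edge-enhancement band
#' profile).
#'
#' @param label_map Integer matrix of 0 (dark patch) and 1 (light patch).
#' @param palette A `patch_palette`.
#' @return A `camo_texture` with `colouration = "flat_disruptive"`.
#' @export
two_tone_from_labels <- function(label_map, palette) {
  stopifnot(is.matrix(label_map), all(label_map %in% c(0L, 1L)))
  img <- array(0, c(nrow(label_map), ncol(label_map), 3L))
  for (k in 1:3) {
    img[, , k] <- ifelse(label_map == 1L, palette$colour_b$srgb[k],
                         palette$colour_a$srgb[k])
  }
  new_camo_texture(img, label_map, "flat_disruptive", palette = palette)
}

#' Radially averaged power spectrum of a texture's pre-posterisation field
#'
#' Bins `|FFT|^2` by radial frequency in bins of width `1/size` cycles/pixel;
#' used to verify that synthesis concentrates power at the filter peak.
#'
#' @param texture A `camo_texture` carrying `$field`.
#' @return A tibble with `freq` (bin centre, cycles/pixel) and `power`.
#' @export
texture_power_spectrum <- function(texture) {
  stopifnot(inherits(texture, "camo_texture"), !is.null(texture$field))
  n <- nrow(texture$field)
  p <- Mod(stats::fft(texture$field))^2
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  d <- sqrt(outer(f^2, f^2, `+`))
  bin <- round(d * n)
  agg <- tapply(as.vector(p), as.vector(bin), mean)
  tibble::tibble(freq = as.numeric(names(agg)) / n, power = as.numeric(agg))
}
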