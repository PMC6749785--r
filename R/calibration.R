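#' Display calibration: pixels <-> degrees of visual angle
#'
#' A calibration couples a viewing distance with a pixel pitch so that image
#' measurements can be expressed in degrees of visual angle. The default
#' geometry is a 1,024-px stimulus subtending 29.86 degrees viewed from 60 cm,
#' with full-extent arctangent geometry (not the small-angle approximation):
#' an extent of `n` pixels subtends `2 * atan(n * pitch / (2 * distance))`.
#'
#' @param extent_px Number of pixels spanning the calibrated extent.
#' @param extent_deg Visual angle of that extent, in degrees (0 < x < 180).
#' @param distance_mm Viewing distance in millimetres.
#' @return A `display_calibration` object with fields `distance_mm` and
#'   `pixel_pitch_mm`.
#' @examples
#' cal <- calibration_from_extent(1024, 29.86, 600)
#' px_to_deg(cal, 82)   # ~2.44 degrees
#' deg_to_px(cal, 9.73) # ~327 px
#' @export
calibration_from_extent <- function(extent_px, extent_deg, distance_mm = 600) {
  if (!is.numeric(extent_px) || length(extent_px) != 1L || extent_px <= 0 ||
      !is.numeric(extent_deg) || length(extent_deg) != 1L || extent_deg <= 0 ||
      extent_deg >= 180 ||
      !is.numeric(distance_mm) || length(distance_mm) != 1L || distance_mm <= 0) {
    stop("invalid calibration: extent_px, distance_mm must be > 0 and ",
         "0 < extent_deg < 180", call. = FALSE)
  }
  pitch <- 2 * distance_mm * tan(extent_deg * pi / 360) / extent_px
  structure(
    list(distance_mm = distance_mm, pixel_pitch_mm = pitch),
    class = "display_calibration"
  )
}

#' @export
print.display_calibration <- function(x, ...) {
  cat(sprintf("<display_calibration> distance %.0f mm, pitch %.4f mm/px\n",
              x$distance_mm, x$pixel_pitch_mm))
  invisible(x)
}

#' Default stimulus calibration
#'
#' The canonical geometry: 1,024 px = 29.86 degrees at 600 mm. Under this
#' calibration the 82-px baseline snake width subtends 2.44 degrees.
#' @return A `display_calibration`.
#' @export
default_calibration <- function() calibration_from_extent(1024, 29.86, 600)

#' Convert a pixel extent to degrees of visual angle
#' @param cal A `display_calibration`.
#' @param npx Pixel extent(s), >= 0. Vectorised.
#' @return Degrees of visual angle.
#' @export
px_to_deg <- function(cal, npx) {
  stopifnot(inherits(cal, "display_calibration"))
  if (any(npx < 0)) stop("npx must be >= 0", call. = FALSE)
  2 * atan(npx * cal$pixel_pitch_mm / (2 * cal$distance_mm)) * 180 / pi
}

#' Convert degrees of visual angle to a (fractional) pixel extent
#' @param cal A `display_calibration`.
#' @param angle_deg Angle(s) in degrees, in `[0, 180)`. Vectorised.
#' @return Fractional pixel counts; exact inverse of [px_to_deg()].
#' @export
deg_to_px <- function(cal, angle_deg) {
  stopifnot(inherits(cal, "display_calibration"))
  if (any(angle_deg < 0 | angle_deg >= 180)) {
    stop("angle_deg must lie in [0, 180)", call. = FALSE)
  }
  2 * cal$distance_mm * tan(angle_deg * pi / 360) / cal$pixel_pitch_mm
}
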