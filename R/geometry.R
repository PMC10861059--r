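#' Screen and stimulus geometry
#'
#' Describes the physical viewing setup (screen size in pixels and
#' centimetres, viewing distance) together with the stimulus resolution and
#' the affine mapping that places the stimulus on the screen. All angular
#' constants used by the fixation filter (merge radius, smoothing bandwidth)
#' are converted to pixels through this object.
#'
#' The default display mapping scales the stimulus to fit the screen width
#' while preserving aspect ratio and centres it (letterboxing); the reference
#' setup is a 1281x720 stimulus shown full screen on a 1680x1050 monitor
#' viewed from 60 cm.
#'
#' @param screen_w_px,screen_h_px Screen resolution in pixels.
#' @param screen_w_cm Physical screen width in centimetres.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#' @param stimulus_w_px,stimulus_h_px Stimulus resolution in pixels.
#' @param display_mapping Optional list with elements `scale`, `offset_x`,
#'   `offset_y` giving the stimulus-to-screen affine transform
#'   (`screen = stimulus * scale + offset`). Computed from the fit-to-width
#'   rule when `NULL`.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' degrees_to_pixels(0.5, geom)
#' @export
screen_geometry <- function(screen_w_px = 1680, screen_h_px = 1050,
                            screen_w_cm = 47.6, viewing_distance_cm = 60,
                            stimulus_w_px = 1281, stimulus_h_px = 720,
                            display_mapping = NULL) {
  dims <- c(screen_w_px, screen_h_px, screen_w_cm, viewing_distance_cm,
            stimulus_w_px, stimulus_h_px)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all geometry dimensions must be finite and > 0")
  if (is.null(display_mapping)) {
    scale <- min(screen_w_px / stimulus_w_px, screen_h_px / stimulus_h_px)
    display_mapping <- list(
      scale = scale,
      offset_x = (screen_w_px - stimulus_w_px * scale) / 2,
      offset_y = (screen_h_px - stimulus_h_px * scale) / 2
    )
  }
  g <- structure(list(
    screen_w_px = screen_w_px, screen_h_px = screen_h_px,
    screen_w_cm = screen_w_cm, viewing_distance_cm = viewing_distance_cm,
    stimulus_w_px = stimulus_w_px, stimulus_h_px = stimulus_h_px,
    display_mapping = display_mapping,
    px_per_cm = screen_w_px / screen_w_cm
  ), class = "screen_geometry")
  stopifnot(is.finite(degrees_to_pixels(1, g)), degrees_to_pixels(1, g) > 0)
  g
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> screen %dx%d px (%.1f cm wide) at %.0f cm\n",
              x$screen_w_px, x$screen_h_px, x$screen_w_cm,
              x$viewing_distance_cm))
  cat(sprintf("  stimulus %dx%d px, display scale %.4f; 1 deg = %.2f px\n",
              x$stimulus_w_px, x$stimulus_h_px, x$display_mapping$scale,
              degrees_to_pixels(1, x)))
  invisible(x)
}

#' Convert visual angle to on-screen pixels
#'
#' Uses the exact chord formula `2 * d * tan(angle/2) * px_per_cm`, so the
#' conversion round-trips with [pixels_to_degrees()] to machine precision.
#'
#' @param angle_deg Visual angle in degrees (non-negative).
#' @param geometry A [screen_geometry()] object.
#' @return Length in screen pixels.
#' @export
degrees_to_pixels <- function(angle_deg, geometry) {
  if (any(angle_deg < 0)) stop("angle_deg must be non-negative")
  2 * geometry$viewing_distance_cm * tan(angle_deg * pi / 360) *
    geometry$px_per_cm
}

#' Convert on-screen pixels to visual angle
#'
#' Inverse of [degrees_to_pixels()].
#'
#' @param px Length in screen pixels (non-negative).
#' @inheritParams degrees_to_pixels
#' @return Visual angle in degrees.
#' @export
pixels_to_degrees <- function(px, geometry) {
  if (any(px < 0)) stop("px must be non-negative")
  2 * atan(px / (2 * geometry$viewing_distance_cm * geometry$px_per_cm)) *
    180 / pi
}

#' Angular conversion in stimulus-pixel units
#'
#' When analysis runs in stimulus coordinates (possibly at reduced stimulus
#' resolution), one degree of visual angle corresponds to
#' `degrees_to_pixels(1) / display_scale` stimulus pixels. These helpers wrap
#' that correction.
#'
#' @inheritParams degrees_to_pixels
#' @return Stimulus-pixel length, or degrees for the inverse.
#' @export
degrees_to_stimulus_px <- function(angle_deg, geometry) {
  degrees_to_pixels(angle_deg, geometry) / geometry$display_mapping$scale
}

#' @rdname degrees_to_stimulus_px
#' @param px Length in stimulus pixels.
#' @export
stimulus_px_to_degrees <- function(px, geometry) {
  pixels_to_degrees(px * geometry$display_mapping$scale, geometry)
}

# stimulus -> screen coordinates
stimulus_to_screen <- function(x, y, geometry) {
  m <- geometry$display_mapping
  list(x = x * m$scale + m$offset_x, y = y * m$scale + m$offset_y)
}

# screen -> stimulus coordinates
screen_to_stimulus <- function(x, y, geometry) {
  m <- geometry$display_mapping
  list(x = (x - m$offset_x) / m$scale, y = (y - m$offset_y) / m$scale)
}
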