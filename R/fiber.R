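#' Tilted carbon-microfiber phantom specification
#'
#' A thin absorbing fiber spanning the field of view at an angle to the
#' scanning plane: its depth changes linearly by `depth_span` over the
#' `horizontal_span` (defaults: 2 mm drop over 5 mm for a 7-um fiber).
#'
#' @param diameter Fiber diameter in um.
#' @param depth_span Vertical extent of the tilt in mm.
#' @param horizontal_span Lateral extent of the fiber in mm.
#' @return A `fiber_spec`.
#' @export
fiber_spec <- function(diameter = 7, depth_span = 2, horizontal_span = 5) {
  if (diameter <= 0 || depth_span <= 0 || horizontal_span <= 0)
    .stop2("all fiber dimensions must be positive", "ringpam_parameter_error")
  structure(list(diameter = diameter, depth_span = depth_span,
                 horizontal_span = horizontal_span),
            class = "fiber_spec")
}

#' Lateral scan pattern
#'
#' @param step_xy Scan step in um.
#' @param extent_xy Field of view `c(x, y)` in mm.
#' @return A `scan_pattern`.
#' @export
scan_pattern <- function(step_xy = 20, extent_xy = c(5, 0.2)) {
  if (step_xy <= 0 || any(extent_xy <= 0))
    .stop2("scan step and extents must be positive",
           "ringpam_parameter_error")
  structure(list(step_xy = step_xy, extent_xy = extent_xy),
            class = "scan_pattern")
}

#' Band-limited echo wavelet
#'
#' Gated derivative-of-Gaussian wavelet used as the per-point axial impulse
#' response of the synthetic A-scan generator; its spectrum peaks near
#' `band / 2` and is essentially contained below `band` MHz.
#'
#' @param t Time axis in us, centred on the echo arrival.
#' @param band Nominal bandwidth in MHz (default 30).
#' @return Numeric vector of wavelet samples (unit peak).
#' @export
dog_wavelet <- function(t, band = 30) {
  sigma <- 1 / (pi * band)                  # us; peak frequency ~ band/2
  w <- -t / sigma * exp(0.5 - t^2 / (2 * sigma^2))
  w[abs(t) > 5 * sigma] <- 0
  w
}

#' Synthetic A-scan stack of the tilted-fiber phantom
#'
#' Generates the volume a scanning ring-detector system would record from a
#' tilted fiber: at every scan position over the fiber, one echo whose
#' arrival time follows the ring time-of-flight rule
#' `t = sqrt(z(x)^2 + r^2) / c` with the fiber's linear depth profile
#' `z(x)`, a Gaussian lateral sensitivity profile across the fiber, constant
#' amplitude along the fiber, plus additive white Gaussian noise.
#'
#' @param fiber A [fiber_spec()].
#' @param scan A [scan_pattern()] (extent must cover the fiber span).
#' @param noise_rms Additive noise RMS relative to unit echo amplitude
#'   (>= 0).
#' @param depth_offset Depth of the shallow fiber end below the ring plane,
#'   in mm.
#' @param ring_radius,sound_speed Ring time-of-flight parameters
#'   (mm, mm/us).
#' @param dt Sample interval in us.
#' @param band Wavelet bandwidth in MHz (see [dog_wavelet()]).
#' @param psf_sigma Lateral (y) sensitivity sigma in um.
#' @param seed Integer seed for the noise.
#' @return An [ascan_volume()]; the generating ground truth is attached as
#'   attribute `truth`.
#' @export
build_fiber_ascan_stack <- function(fiber = fiber_spec(),
                                    scan = scan_pattern(),
                                    noise_rms = 0,
                                    depth_offset = 0.3,
                                    ring_radius = 2.3, sound_speed = 1.5,
                                    dt = 0.001, band = 30,
                                    psf_sigma = 10, seed = 1L) {
  stopifnot(inherits(fiber, "fiber_spec"), inherits(scan, "scan_pattern"))
  if (noise_rms < 0)
    .stop2("`noise_rms` must be >= 0", "ringpam_parameter_error")
  if (scan$extent_xy[1] < fiber$horizontal_span)
    .stop2("scan extent must cover the fiber horizontal span",
           "ringpam_geometry_error")
  step_mm <- scan$step_xy / 1000
  x <- seq(0, scan$extent_xy[1], by = step_mm)
  y <- seq(0, scan$extent_xy[2], by = step_mm)
  slope <- fiber$depth_span / fiber$horizontal_span
  z_of_x <- depth_offset + slope * pmin(x, fiber$horizontal_span)
  t_arr <- depth_to_time(z_of_x, ring_radius, sound_speed)
  y0 <- mean(range(y))                       # fiber runs along x at y = y0
  amp_y <- exp(-(y - y0)^2 / (2 * (psf_sigma / 1000)^2))
  t_end <- max(t_arr) + 0.3
  nt <- as.integer(ceiling(t_end / dt))
  t_axis <- seq_len(nt) * dt
  vol <- array(0, dim = c(length(x), length(y), nt))
  for (ix in seq_along(x)) {
    on_fiber <- x[ix] <= fiber$horizontal_span
    if (on_fiber) {
      wav <- dog_wavelet(t_axis - t_arr[ix], band = band)
      for (iy in seq_along(y)) vol[ix, iy, ] <- amp_y[iy] * wav
    }
  }
  if (noise_rms > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(length(vol), sd = noise_rms), dim(vol))
  }
  out <- ascan_volume(vol, dt = dt, scan_step = scan$step_xy)
  attr(out, "truth") <- tibble::tibble(x = x, z = z_of_x, t = t_arr)
  out
}
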