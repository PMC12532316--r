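#' Nonlinear time-to-depth transform for a ring detector
#'
#' For a ring-shaped detector of radius `r`, an on-axis source at depth `z`
#' below the ring plane is heard at time `t = sqrt(z^2 + r^2) / c`, so depth
#' follows from arrival time as `z = sqrt(c^2 t^2 - r^2)` - a nonlinear
#' transform rather than a simple multiplication by the sound speed.
#'
#' @param t Arrival times in us.
#' @param ring_radius Ring radius r in mm (default 2.3).
#' @param sound_speed Sound speed c in mm/us (default 1.5, water).
#' @return Depths z in mm, measured from the ring plane.
#' @examples
#' time_to_depth(2.3 / 1.5)       # boundary of the domain: z = 0
#' time_to_depth(2.75 / 1.5)      # the focal radius maps near the working distance
#' @export
time_to_depth <- function(t, ring_radius = 2.3, sound_speed = 1.5) {
  ct <- sound_speed * t
  if (any(ct < ring_radius - 1e-12))
    .stop2("c * t < r: arrival earlier than the ring radius allows (out of domain)",
           "ringpam_domain_error")
  sqrt(pmax(0, ct^2 - ring_radius^2))
}

#' @rdname time_to_depth
#' @param z Depths in mm.
#' @export
depth_to_time <- function(z, ring_radius = 2.3, sound_speed = 1.5) {
  sqrt(z^2 + ring_radius^2) / sound_speed
}

#' Hilbert envelope of a trace
#'
#' Magnitude of the analytic signal, computed spectrally: the negative
#' frequency half of the spectrum is zeroed (positive half doubled) and the
#' magnitude of the inverse transform taken.  The envelope is non-negative
#' and bounds the rectified signal.
#'
#' @param x Numeric vector, a matrix with time along rows, or a 3D array
#'   with time along the third axis.
#' @return Same shape as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' range(envelope(sin(2 * pi * 50 * t))[100:900])
#' @export
envelope <- function(x) {
  env1 <- function(v) {
    n <- length(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1; h[2:((n + 1) / 2)] <- 2
    }
    Mod(fft(fft(v) * h, inverse = TRUE) / n)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    out <- apply(x, c(1, 2), env1)          # time moves to the first axis
    return(aperm(out, c(2, 3, 1)))
  }
  if (is.matrix(x)) return(apply(x, 2, env1))
  env1(as.numeric(x))
}

#' Zero-phase low-pass for A-scan volumes
#'
#' Shared implementation with [apply_band_limit()]: forward-backward
#' 4th-order Butterworth at `cutoff` (default 30 MHz, the cut-off used to
#' suppress high-frequency noise before envelope detection).
#'
#' @param x Numeric vector, matrix (time along rows), 3D array (time along
#'   the third axis) or an `ascan_volume`.
#' @param cutoff Cut-off frequency in MHz.
#' @param dt Sample interval in us (taken from the volume when available).
#' @return Same type as `x`.
#' @export
lowpass <- function(x, cutoff = 30, dt = NULL) {
  if (inherits(x, "ascan_volume")) {
    x$samples <- lowpass(x$samples, cutoff, x$dt)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    stopifnot(!is.null(dt))
    out <- apply(x, c(1, 2), function(v) .lowpass_num(v, cutoff, dt))
    return(aperm(out, c(2, 3, 1)))
  }
  stopifnot(!is.null(dt))
  .lowpass_num(x, cutoff, dt)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum along one axis of a (typically envelope-detected,
#' non-negative) volume.  `NA` samples (e.g. masked out-of-domain depths) are
#' ignored; pixels whose entire column is masked come back as `NA`.
#'
#' @param volume 3D array, `ascan_volume` or `depth_volume`.
#' @param axis Axis to project along: 3 (default; depth/time) gives an
#'   en-face image, 2 gives a B-scan-like x-depth image.
#' @return A 2D matrix.
#' @export
mip <- function(volume, axis = 3) {
  v <- if (inherits(volume, c("ascan_volume", "depth_volume")))
    volume$samples else volume
  stopifnot(is.array(v), length(dim(v)) == 3, axis %in% 1:3)
  keep <- setdiff(1:3, axis)
  suppressWarnings(out <- apply(v, keep, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Spectrum statistics of a mean trace
#'
#' Magnitude spectrum of the Hann-windowed trace: peak frequency and the
#' contiguous bandwidth at -20 dB relative to the peak.
#'
#' @param trace Numeric vector (>= 64 samples).
#' @param dt Sample interval in us.
#' @return A one-row tibble with `peak_frequency`, `width_minus20db`, `f_lo`,
#'   `f_hi` (MHz) and a `degenerate` flag set when the -20 dB band touches
#'   the edge of the analysed band (e.g. white noise).
#' @export
spectrum_stats <- function(trace, dt) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 64)
    .stop2("trace must have at least 64 samples", "ringpam_parameter_error")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))    # Hann
  sp <- Mod(fft(trace * w))[1:(n %/% 2 + 1)]
  # light running-mean smoothing of the magnitude: width statistics of a
  # noisy spectrum are meaningless on raw periodogram bins
  ks <- 5L; kh <- ks %/% 2L
  padded <- c(rep(sp[1], kh), sp, rep(sp[length(sp)], kh))
  sp <- as.numeric(stats::filter(padded, rep(1 / ks, ks),
                                 sides = 2))[(kh + 1):(kh + length(sp))]
  f <- seq(0, by = 1 / (n * dt) , length.out = n %/% 2 + 1)  # MHz
  ipk <- which.max(sp)
  thr <- sp[ipk] * 10^(-20 / 20)
  lo <- ipk; while (lo > 1 && sp[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk; while (hi < length(sp) && sp[hi + 1] >= thr) hi <- hi + 1
  interp <- function(i1, i2) {
    if (i1 == i2) return(f[i1])
    f[i1] + (thr - sp[i1]) / (sp[i2] - sp[i1]) * (f[i2] - f[i1])
  }
  f_lo <- if (lo > 1) interp(lo - 1, lo) else f[1]
  f_hi <- if (hi < length(sp)) interp(hi + 1, hi) else f[length(sp)]
  tibble::tibble(peak_frequency = f[ipk], width_minus20db = f_hi - f_lo,
                 f_lo = f_lo, f_hi = f_hi,
                 degenerate = (lo == 1 && ipk > 1) || hi == length(sp))
}

#' Closed-form axial resolution of a bandwidth-limited detector
#'
#' `RA = 0.88 c / delta_f`: the axial point-spread width supported by a
#' detection bandwidth `delta_f`.
#'
#' @param delta_f Bandwidth in MHz (> 0).
#' @param sound_speed Sound speed in mm/us.
#' @return Axial resolution in um.
#' @examples
#' axial_resolution(28)   # about 47 um at c = 1.5 mm/us
#' @export
axial_resolution <- function(delta_f, sound_speed = 1.5) {
  if (any(delta_f <= 0))
    .stop2("`delta_f` must be positive", "ringpam_parameter_error")
  0.88 * sound_speed / delta_f * 1000
}

#' Closed-form optical focal waist
#'
#' `w0 ~ 0.5 lambda / NA`: the focal spot width of the focusing optics.
#'
#' @param wavelength Optical wavelength in nm.
#' @param na_opt Numerical aperture of the lens (> 0).
#' @return Waist width in um.
#' @examples
#' focal_waist(532, 0.06)   # about 4.4 um
#' @export
focal_waist <- function(wavelength = 532, na_opt = 0.06) {
  if (any(na_opt <= 0))
    .stop2("`na_opt` must be positive", "ringpam_parameter_error")
  0.5 * wavelength * 1e-3 / na_opt
}

#' Lateral FWHM of a B-scan profile
#'
#' Width of the dominant peak of one lateral line of an envelope-detected
#' B-scan, in physical units.  Errors when two disjoint regions reach the
#' peak level (ambiguous profile).
#'
#' @param bscan Matrix with the lateral coordinate along rows.
#' @param row Index along the second (depth/time) axis.
#' @param step Lateral sample step in um.
#' @return FWHM in um.
#' @export
lateral_fwhm_profile <- function(bscan, row, step) {
  v <- bscan[, row]
  vmax <- max(v)
  at_max <- which(v > 0.999 * vmax)
  if (any(diff(at_max) > 1) )
    .stop2("two or more equal peaks: lateral profile is ambiguous",
           "ringpam_ambiguous_peak")
  fwhm.default(seq_along(v) * step, v)
}

#' A-scan volume container
#'
#' @param samples 3D array (x, y, t).
#' @param dt Sample interval in us.
#' @param scan_step Lateral scan step in um.
#' @param t0 Time of the first sample in us (default `dt`).
#' @return An `ascan_volume`.
#' @export
ascan_volume <- function(samples, dt, scan_step, t0 = dt) {
  stopifnot(is.array(samples), length(dim(samples)) == 3, dt > 0,
            scan_step >= 0)
  structure(list(samples = samples, dt = dt, scan_step = scan_step, t0 = t0),
            class = "ascan_volume")
}

#' @export
print.ascan_volume <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<ascan_volume> %d x %d scan positions x %d samples, dt = %g us, step = %g um\n",
    d[1], d[2], d[3], x$dt, x$scan_step))
  invisible(x)
}

#' Map an A-scan volume onto a uniform depth axis
#'
#' Resamples every A-scan from its time axis onto a regular depth grid using
#' the ring time-to-depth transform [time_to_depth()]; linear interpolation,
#' with samples at `c t < r` (no physical depth) masked as `NA` rather than
#' fabricated.
#'
#' @param volume An [ascan_volume()].
#' @param ring_radius Ring radius in mm.
#' @param sound_speed Sound speed in mm/us.
#' @param dz Depth step in mm (default `sound_speed * dt`).
#' @return A `depth_volume`: samples (x, y, z), `dz` and `z` axis in mm.
#' @export
map_depth <- function(volume, ring_radius = 2.3, sound_speed = 1.5,
                      dz = NULL) {
  stopifnot(inherits(volume, "ascan_volume"))
  d <- dim(volume$samples)
  t_axis <- volume$t0 + (seq_len(d[3]) - 1) * volume$dt
  valid <- sound_speed * t_axis >= ring_radius
  if (!any(valid))
    .stop2("no sample satisfies c t >= r; nothing to map",
           "ringpam_domain_error")
  if (is.null(dz)) dz <- sound_speed * volume$dt
  z_max <- time_to_depth(max(t_axis), ring_radius, sound_speed)
  z <- seq(0, z_max, by = dz)
  t_of_z <- depth_to_time(z, ring_radius, sound_speed)
  out <- array(NA_real_, dim = c(d[1], d[2], length(z)))
  for (iy in seq_len(d[2])) {
    for (ix in seq_len(d[1])) {
      out[ix, iy, ] <- approx(t_axis, volume$samples[ix, iy, ],
                              xout = t_of_z, rule = 1)$y
    }
  }
  structure(list(samples = out, dz = dz, z = z,
                 ring_radius = ring_radius, sound_speed = sound_speed,
                 scan_step = volume$scan_step),
            class = "depth_volume")
}

#' @export
print.depth_volume <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<depth_volume> %d x %d scan positions x %d depths, dz = %g mm\n",
    d[1], d[2], d[3], x$dz))
  invisible(x)
}
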