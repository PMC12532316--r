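# Shared zero-phase low-pass used by the detector band-limit and the A-scan
# processing chain: 4th-order Butterworth, applied forward-backward
# (signal::filtfilt), so the pass band keeps zero phase delay.

.lowpass_filter <- function(cutoff, dt) {
  nyquist <- 1 / (2 * dt)                     # MHz when dt is in us
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= nyquist)
    .stop2(sprintf("`cutoff` must be in (0, %g) MHz", nyquist),
           "ringpam_parameter_error")
  signal::butter(4, cutoff / nyquist, type = "low")
}

.lowpass_num <- function(x, cutoff, dt) {
  bf <- .lowpass_filter(cutoff, dt)
  # reflective end padding removes filtfilt edge transients (so that e.g. a
  # constant trace passes through unchanged)
  nyquist <- 1 / (2 * dt)
  ff <- function(v) {
    n <- length(v)
    # the endpoint ramp (DC + slope, both deep in the pass band) bypasses
    # the filter exactly; the residual starts and ends at zero, so the
    # reflective padding leaves no start-up transient
    ramp <- seq(v[1], v[n], length.out = n)
    r <- v - ramp
    np <- min(n - 1, max(48L, ceiling(3 * nyquist / cutoff)))
    rp <- c(2 * r[1] - r[(np + 1):2], r, 2 * r[n] - r[(n - 1):(n - np)])
    ramp + signal::filtfilt(bf, rp)[(np + 1):(np + n)]
  }
  if (is.matrix(x)) apply(x, 2, ff) else ff(x)
}

#' Band-limit a signal with a zero-phase low-pass
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth low-pass at
#' `cutoff` to a trace set or an aggregated detector signal; signal energy
#' never increases.  Used to emulate a detector with a limited reception
#' bandwidth (about 30 MHz in the experimentally realised device).
#'
#' @param x A `pressure_traces`, `detector_signal`, numeric vector, or a
#'   matrix with time along rows.
#' @param cutoff Cut-off frequency in MHz (must be below Nyquist,
#'   500 MHz at dt = 1 ns).
#' @param dt Sample interval in us (required for plain vectors/matrices).
#' @param ... Unused.
#' @return An object of the same type as `x`.
#' @export
apply_band_limit <- function(x, cutoff, ...) UseMethod("apply_band_limit")

#' @rdname apply_band_limit
#' @export
apply_band_limit.default <- function(x, cutoff, dt, ...) {
  .lowpass_num(x, cutoff, dt)
}

#' @rdname apply_band_limit
#' @export
apply_band_limit.pressure_traces <- function(x, cutoff, ...) {
  x$traces <- .lowpass_num(x$traces, cutoff, x$dt)
  x$band_limit <- cutoff
  x
}

#' @rdname apply_band_limit
#' @export
apply_band_limit.detector_signal <- function(x, cutoff, ...) {
  x$samples <- .lowpass_num(x$samples, cutoff, x$dt)
  x$amplitude_pp <- max(x$samples) - min(x$samples)
  x$amplitude_env <- max(envelope(x$samples))
  x$band_limit <- cutoff
  x
}
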