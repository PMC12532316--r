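#' Acoustic reception field along the detector axis
#'
#' Detector response amplitude as a function of the axial position of a
#' point source; the FWHM of this field is the acoustic depth of field
#' (DOF).  Two routes are provided:
#'
#' * `"reciprocity"` (default, one run): the transmit field of the active
#'   aperture equals its receive sensitivity map, so one propagation with the
#'   initial pressure placed on the active arc gives the field amplitude at
#'   every axial position at once.
#' * `"per_z_source"` (reference): one propagation per axial source
#'   position, aggregating the element traces; slower, used for
#'   cross-checking the reciprocity route.
#'
#' @param geom A [ring_geometry()].
#' @param z_range Axial interval in mm, relative to the focus (positive away
#'   from the detector).
#' @param n_z Number of axial sample positions.
#' @param method `"reciprocity"` or `"per_z_source"`.
#' @param band_limit Optional low-pass cut-off in MHz applied to the traces
#'   before the amplitude measurement.
#' @param medium An [acoustic_medium()].
#' @param dx,dt,pml Grid parameters.
#' @param spacing Arc discretization step in mm.
#' @param level Relative level defining the DOF width (default 0.5, i.e.
#'   FWHM).
#' @param metric Amplitude summary per axial position: `"envelope"`
#'   (Hilbert-envelope maximum, default) or `"peak_to_peak"`.
#' @param probe_diameter Diameter (um) of the small spherical source used
#'   to probe the field, or `NULL` (default) for an ideal one-cell point
#'   source.  A finite probe band-limits the response through its transit
#'   time and widens the measured field; in the reciprocity route it is
#'   applied as the disc's chord-projection kernel on the axis signals, in
#'   the per-z route as a source patch of that size.
#' @return A `reception_field`: tibble `field` with columns `z`, `amplitude`,
#'   plus the geometry and `dof_fwhm`.
#' @export
reception_field <- function(geom, z_range = c(-1.4, 1.4), n_z = 57,
                            method = c("reciprocity", "per_z_source"),
                            band_limit = NULL, medium = acoustic_medium(),
                            dx = 0.005, dt = 0.001, pml = 20L,
                            spacing = 0.005, level = 0.5,
                            metric = c("envelope", "peak_to_peak"),
                            probe_diameter = NULL) {
  stopifnot(inherits(geom, "ring_geometry"))
  method <- match.arg(method)
  metric <- match.arg(metric)
  amp_of <- if (metric == "envelope") function(v) max(envelope(v))
            else function(v) max(v) - min(v)
  z <- seq(z_range[1], z_range[2], length.out = n_z)
  R <- geom$focal_radius
  margin <- 0.12

  elements <- sample_elements(geom, spacing = spacing)
  grid <- .grid_covering(
    c(min(elements$x) - margin, max(elements$x) + margin),
    c(min(elements$z) - margin, max(z) + margin),
    dx = dx, dt = dt, pml = pml)
  # paint the active arc(s) onto grid cells once; both routes use exactly
  # this cell set (transmit cells vs receive cells), which makes them
  # numerical adjoints of each other rather than merely similar models
  th <- unique(c(seq(geom$theta_inner, geom$theta_outer, by = dx / R / 2),
                 geom$theta_outer))
  tt <- if (geom$theta_inner > 0) c(-rev(th), th) else
    unique(c(seq(-geom$theta_outer, geom$theta_outer, by = dx / R / 2),
             geom$theta_outer))
  ij <- unique(round(.grid_index(grid, R * sin(tt), -R * cos(tt))),
               MARGIN = 1)
  arc_xz <- cbind(grid$origin[1] + ij[, 1] * grid$dx,
                  grid$origin[2] + ij[, 2] * grid$dx)
  # axial sample positions, snapped to cell centres and reported truthfully
  z <- grid$origin[2] + round((z - grid$origin[2]) / dx) * dx
  dmax <- max(sqrt((R * sin(geom$theta_outer))^2 +
                     (z + R * cos(geom$theta_inner))^2))
  t_end <- (dmax + 0.1) / medium$sound_speed

  if (method == "reciprocity") {
    p0 <- matrix(0, grid$nx, grid$nz)
    p0[ij + 1] <- 1
    src <- initial_pressure(p0, grid)
    tr <- propagate(src, medium,
                    sensor_points(rep(0, n_z), z,
                                  interpolation = "nearest"),
                    t_end = t_end)
    signals <- tr$traces                       # one axis trace per z
    dt_sig <- tr$dt
    if (!is.null(probe_diameter))
      signals <- apply(signals, 2, .probe_smooth, probe_diameter,
                       medium$sound_speed, dt_sig)
  } else {
    d_src <- if (is.null(probe_diameter)) dx * 1000 else probe_diameter
    sig_list <- lapply(z, function(zi) {
      src <- make_line_source(d_src, d_src, grid, center = c(0, zi))
      tr <- propagate(src, medium,
                      sensor_points(arc_xz[, 1], arc_xz[, 2],
                                    interpolation = "nearest"),
                      t_end = t_end)
      rowMeans(tr$traces)
    })
    signals <- do.call(cbind, sig_list)        # aggregation commutes with
    dt_sig <- dt                               # the (linear) low-pass
  }
  if (!is.null(band_limit)) signals <- .lowpass_num(signals, band_limit,
                                                    dt_sig)
  amp <- apply(signals, 2, amp_of)

  field <- tibble::tibble(z = z, amplitude = amp)
  dof <- tryCatch(fwhm.default(field$z, field$amplitude, level = level),
                  ringpam_open_profile = function(e) NA_real_)
  structure(list(field = field, geom = geom, method = method,
                 band_limit = band_limit, dof_fwhm = dof, level = level,
                 metric = metric, signals = signals, dt = dt_sig),
            class = "reception_field")
}

# transit-time kernel of a small disc source: chord-projection profile
.probe_smooth <- function(v, d_um, c0, dt) {
  t_half <- d_um / 1000 / c0 / 2
  tau <- seq(-t_half, t_half, by = dt)
  if (length(tau) < 2) return(v)
  k <- sqrt(pmax(0, 1 - (tau / t_half)^2))
  out <- stats::filter(v, k / sum(k), sides = 2)
  out[is.na(out)] <- 0
  as.numeric(out)
}

#' Re-evaluate a reception field under a different band limit
#'
#' Reuses the axial signals stored in a [reception_field()] result, so no
#' further propagation is needed (the zero-phase low-pass commutes with the
#' linear element aggregation).
#'
#' @param rf A `reception_field`.
#' @param band_limit Low-pass cut-off in MHz, or `NULL` for the full band.
#' @return A new `reception_field`.
#' @export
reband_reception <- function(rf, band_limit) {
  stopifnot(inherits(rf, "reception_field"))
  signals <- rf$signals
  if (!is.null(band_limit)) signals <- .lowpass_num(signals, band_limit,
                                                    rf$dt)
  amp_of <- if (identical(rf$metric, "peak_to_peak"))
    function(v) max(v) - min(v) else function(v) max(envelope(v))
  amp <- apply(signals, 2, amp_of)
  field <- tibble::tibble(z = rf$field$z, amplitude = amp)
  dof <- tryCatch(fwhm.default(field$z, field$amplitude, level = rf$level),
                  ringpam_open_profile = function(e) NA_real_)
  structure(list(field = field, geom = rf$geom, method = rf$method,
                 band_limit = band_limit, dof_fwhm = dof, level = rf$level,
                 metric = rf$metric, signals = rf$signals, dt = rf$dt),
            class = "reception_field")
}

#' @export
print.reception_field <- function(x, ...) {
  cat(sprintf(
    "<reception_field> %d axial positions (%s), DOF (FWHM) = %s mm\n",
    nrow(x$field), x$method,
    ifelse(is.na(x$dof_fwhm), "open", sprintf("%.3f", x$dof_fwhm))))
  invisible(x)
}

#' @export
tidy.reception_field <- function(x, ...) {
  x$field
}

#' @export
glance.reception_field <- function(x, ...) {
  tibble::tibble(dof_fwhm = x$dof_fwhm,
                 z_peak = x$field$z[which.max(x$field$amplitude)],
                 n_z = nrow(x$field), method = x$method,
                 band_limit = if (is.null(x$band_limit)) NA_real_
                              else x$band_limit)
}
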