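#' Detection efficiency versus central aperture diameter
#'
#' Aggregate signal amplitude of ring detectors with increasing central
#' aperture, for one vertically extended source at the focus.  A single
#' propagation per source is reused: each aperture is evaluated by
#' re-aggregating the stored element traces, optionally after a band-limiting
#' low-pass.
#'
#' @param source Either a numeric source length in um (a propagation is run
#'   via [simulate_detection()]) or an existing `detection_run`.
#' @param apertures Central aperture diameters d in mm (each with 0 <= d <
#'   D).
#' @param band_limit Optional low-pass cut-off in MHz.
#' @param geom Base [ring_geometry()] supplying D, R (ignored when `source`
#'   is a run).
#' @param ... Passed to [simulate_detection()] when `source` is a length.
#' @return A tibble with columns `central_aperture`, `amplitude`
#'   (envelope-maximum), `amplitude_pp`, `n_elements`, `band_limit`.
#' @export
sensitivity_sweep <- function(source, apertures, band_limit = NULL,
                              geom = ring_geometry(), ...) {
  run <- if (inherits(source, "detection_run")) source
         else simulate_detection(source, geom = geom, ...)
  geom <- run$geom
  if (any(apertures < 0 | apertures >= geom$outer_aperture))
    .stop2("apertures must satisfy 0 <= d < D", "ringpam_geometry_error")
  tr <- run$traces
  if (!is.null(band_limit)) tr <- apply_band_limit(tr, band_limit)
  rows <- lapply(apertures, function(d) {
    g <- ring_geometry(outer_aperture = geom$outer_aperture,
                       working_distance = geom$working_distance,
                       central_aperture = d)
    cols <- .element_subset(run, g$theta_inner, g$theta_outer)
    sig <- aggregate_elements(tr, columns = cols)
    tibble::tibble(central_aperture = d,
                   amplitude = sig$amplitude_env,
                   amplitude_pp = sig$amplitude_pp,
                   n_elements = length(cols))
  })
  out <- dplyr::bind_rows(rows)
  out$band_limit <- if (is.null(band_limit)) NA_real_ else band_limit
  out
}

#' Signal amplitude versus acoustic numerical aperture
#'
#' Full-aperture (no central hole) detectors of varying angular coverage at a
#' fixed focal radius.  One propagation with elements up to 90 degrees is
#' reused for every NA value.
#'
#' @param source Numeric source length in um or a `detection_run` sampled up
#'   to `max_theta = pi/2`.
#' @param na_values Acoustic numerical apertures in (0, 1].
#' @param focal_radius Focal radius in mm (ignored when `source` is a run).
#' @param band_limit Optional low-pass cut-off in MHz.
#' @param ... Passed to [simulate_detection()].
#' @return A tibble with columns `na`, `amplitude` (envelope-maximum),
#'   `amplitude_pp`, `n_elements`.
#' @export
na_sweep <- function(source, na_values, focal_radius = 2.75,
                     band_limit = NULL, ...) {
  if (any(na_values <= 0 | na_values > 1))
    .stop2("NA values must be in (0, 1]", "ringpam_parameter_error")
  run <- if (inherits(source, "detection_run")) source
         else simulate_detection(source,
                                 geom = ring_geometry(focal_radius = focal_radius,
                                                      na = 1),
                                 max_theta = pi / 2, ...)
  tr <- run$traces
  if (!is.null(band_limit)) tr <- apply_band_limit(tr, band_limit)
  rows <- lapply(na_values, function(a) {
    cols <- .element_subset(run, 0, asin(a))
    sig <- aggregate_elements(tr, columns = cols)
    tibble::tibble(na = a, amplitude = sig$amplitude_env,
                   amplitude_pp = sig$amplitude_pp,
                   n_elements = length(cols))
  })
  dplyr::bind_rows(rows)
}
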