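#' Spherically-focused ring-segment detector geometry
#'
#' Parametric geometry of a spherically focused detector with a circular
#' central aperture (hole).  The focal radius follows from the outer aperture
#' and the working distance, `R = sqrt((D/2)^2 + WD^2)`, and the acoustic
#' numerical aperture is `NA = (D/2) / R`.  With the default D = 4.6 mm and
#' WD = 1.5 mm this gives R = 2.75 mm and NA = 0.84.  Setting `ring_width`
#' selects the thin-ring-segment mode, `d = D - 2 * ring_width`.
#'
#' @param outer_aperture Outer aperture diameter D in mm.
#' @param working_distance Working distance WD in mm (axial distance from the
#'   detector rim plane to the focus).
#' @param central_aperture Central hole diameter d in mm (0 <= d < D).
#' @param ring_width If not `NULL`, active ring width in mm; selects the
#'   thin-ring-segment mode and overrides `central_aperture`.
#' @param ring_width_convention How `ring_width` is measured:
#'   `"surface"` (default) takes it along the spherical detector surface,
#'   `theta_inner = theta_outer - w/R` — the width of the physical film
#'   strip; `"aperture"` takes it on the aperture plane, `d = D - 2w`.
#'   The reception-field length scales as `1/(cos theta_i - cos theta_o)`,
#'   so the two readings differ materially for thin rings.
#' @param focal_radius,na Alternative parametrisation: give `focal_radius`
#'   (mm) together with `na` instead of `outer_aperture` +
#'   `working_distance`.
#' @return A `ring_geometry` object with the derived focal radius, NA,
#'   working distance and arc angles (radians from the detector axis).
#' @examples
#' ring_geometry()                      # full-aperture reference detector
#' ring_geometry(ring_width = 0.1)      # thin 100-um ring segment
#' @export
ring_geometry <- function(outer_aperture = 4.6, working_distance = 1.5,
                          central_aperture = 0, ring_width = NULL,
                          ring_width_convention = c("surface", "aperture"),
                          focal_radius = NULL, na = NULL) {
  ring_width_convention <- match.arg(ring_width_convention)
  if (!is.null(focal_radius) || !is.null(na)) {
    if (is.null(focal_radius) || is.null(na))
      .stop2("give both `focal_radius` and `na`", "ringpam_parameter_error")
    if (na <= 0 || na > 1)
      .stop2("`na` must be in (0, 1]", "ringpam_parameter_error")
    R <- focal_radius
    D <- 2 * R * na
    WD <- R * sqrt(max(0, 1 - na^2))
  } else {
    if (outer_aperture <= 0 || working_distance <= 0)
      .stop2("aperture and working distance must be positive",
             "ringpam_parameter_error")
    D <- outer_aperture
    WD <- working_distance
    R <- sqrt((D / 2)^2 + WD^2)
  }
  if (!is.null(ring_width)) {
    if (ring_width <= 0 || 2 * ring_width > D)
      .stop2("`ring_width` must be in (0, D/2]", "ringpam_parameter_error")
    if (ring_width_convention == "aperture") {
      central_aperture <- D - 2 * ring_width
    } else {
      theta_o <- asin(pmin(1, (D / 2) / R))
      theta_i <- max(0, theta_o - ring_width / R)
      central_aperture <- 2 * R * sin(theta_i)
    }
  }
  d <- central_aperture
  if (d < 0 || d >= D)
    .stop2("central aperture must satisfy 0 <= d < D (empty active area)",
           "ringpam_geometry_error")
  structure(list(
    focal_radius = R, outer_aperture = D, central_aperture = d,
    working_distance = WD, na = (D / 2) / R,
    ring_width = if (is.null(ring_width)) (D - d) / 2 else ring_width,
    theta_outer = asin(pmin(1, (D / 2) / R)),
    theta_inner = asin(pmin(1, (d / 2) / R))
  ), class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(
    "<ring_geometry> R = %.3f mm, D = %.2f mm, d = %.2f mm, WD = %.3f mm, NA = %.3f\n",
    x$focal_radius, x$outer_aperture, x$central_aperture,
    x$working_distance, x$na))
  cat(sprintf("  arc: %.1f..%.1f degrees from the axis (both signs)\n",
              x$theta_inner * 180 / pi, x$theta_outer * 180 / pi))
  invisible(x)
}

#' @export
tidy.ring_geometry <- function(x, ...) {
  tibble::tibble(focal_radius = x$focal_radius,
                 outer_aperture = x$outer_aperture,
                 central_aperture = x$central_aperture,
                 working_distance = x$working_distance, na = x$na,
                 theta_inner_deg = x$theta_inner * 180 / pi,
                 theta_outer_deg = x$theta_outer * 180 / pi)
}

#' Discretize the active detector arc into elements
#'
#' Places uniformly spaced sample points on the active arc segments of the
#' detector in the simulation (x-z) plane: a single contiguous arc when the
#' central aperture is zero, two symmetric segments otherwise.  The focus is
#' at the origin; element positions are `(R sin(theta), -R cos(theta))`.
#' Weights are arc-length weights, normalised to sum to 1.
#'
#' @param geom A [ring_geometry()].
#' @param spacing Arc-length spacing between elements in mm (default 0.005).
#' @param n_elements Alternative to `spacing`: total element count.
#' @return An `element_sampling` tibble with columns `theta`, `x`, `z`,
#'   `weight`.
#' @export
sample_elements <- function(geom, spacing = 0.005, n_elements = NULL) {
  stopifnot(inherits(geom, "ring_geometry"))
  R <- geom$focal_radius
  ti <- geom$theta_inner; to <- geom$theta_outer
  if (to <= ti)
    .stop2("active arc is empty (d >= D)", "ringpam_geometry_error")
  if (ti == 0) {
    n <- if (is.null(n_elements)) max(3L, ceiling(2 * to * R / spacing) + 1L)
         else as.integer(n_elements)
    if (n < 2) .stop2("need at least 2 elements", "ringpam_parameter_error")
    theta <- seq(-to, to, length.out = n)
  } else {
    n1 <- if (is.null(n_elements))
      max(2L, ceiling((to - ti) * R / spacing) + 1L)
    else max(2L, as.integer(round(n_elements / 2)))
    th <- seq(ti, to, length.out = n1)
    theta <- c(-rev(th), th)
  }
  structure(tibble::tibble(theta = theta, x = R * sin(theta),
                           z = -R * cos(theta),
                           weight = 1 / length(theta)),
            class = c("element_sampling", "tbl_df", "tbl", "data.frame"),
            geom = geom)
}

#' Aggregate element traces into one detector signal
#'
#' The detector output is modelled as the arc-length-weighted mean of the
#' element pressures (a pressure-averaging receiver): all elements are
#' equidistant (R) from the focus, so focal arrivals add coherently with no
#' extra delays.  Two amplitude summaries are attached: the Hilbert-envelope
#' maximum (`amplitude_env`, the canonical detector amplitude here, matching
#' how optoacoustic signal maxima are normally measured) and the raw
#' peak-to-peak (`amplitude_pp`).
#'
#' @param traces A `pressure_traces` with one trace per element.
#' @param elements The matching [sample_elements()] tibble (defaults to all
#'   traces with equal weights).
#' @param columns Optional integer subset: which trace columns belong to the
#'   elements (used when re-aggregating a stored dense trace set).
#' @return A `detector_signal` with the aggregated `samples` and the
#'   peak-to-peak `amplitude_pp`.
#' @export
aggregate_elements <- function(traces, elements = NULL, columns = NULL) {
  stopifnot(inherits(traces, "pressure_traces"))
  m <- traces$traces
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  if (is.null(elements)) {
    w <- rep(1 / ncol(m), ncol(m))
  } else {
    if (nrow(elements) != ncol(m))
      .stop2("trace/element count mismatch", "ringpam_parameter_error")
    w <- elements$weight / sum(elements$weight)
  }
  s <- as.vector(m %*% w)
  structure(list(samples = s, dt = traces$dt, t = traces$t,
                 amplitude_pp = max(s) - min(s),
                 amplitude_env = max(envelope(s)),
                 n_elements = length(w)),
            class = "detector_signal")
}

#' Detector signal amplitude
#'
#' @param x A `detector_signal`.
#' @param metric `"envelope"` (Hilbert-envelope maximum, default) or
#'   `"peak_to_peak"`.
#' @return Scalar amplitude.
#' @export
amplitude <- function(x, metric = c("envelope", "peak_to_peak")) {
  stopifnot(inherits(x, "detector_signal"))
  metric <- match.arg(metric)
  if (metric == "envelope") x$amplitude_env else x$amplitude_pp
}

#' @export
print.detector_signal <- function(x, ...) {
  cat(sprintf(
    "<detector_signal> %d samples, dt = %g us, envelope max %.4g, peak-to-peak %.4g (%d elements)\n",
    length(x$samples), x$dt, x$amplitude_env, x$amplitude_pp,
    x$n_elements))
  invisible(x)
}

#' @export
tidy.detector_signal <- function(x, ...) {
  tibble::tibble(t = x$t, value = x$samples)
}

#' Peak-to-peak amplitude
#'
#' @param x A `detector_signal` or numeric vector.
#' @return `max(x) - min(x)`.
#' @export
amplitude_pp <- function(x) {
  if (inherits(x, "detector_signal")) return(x$amplitude_pp)
  max(x) - min(x)
}

#' Simulate detection of a vertical line source at the focus
#'
#' Runs one 2D propagation of an axially extended initial-pressure source
#' placed at the detector focus, recording the pressure at a dense set of
#' element positions on the detector arc.  The stored element traces can then
#' be re-aggregated for any central aperture, angular coverage or bandwidth
#' without further propagation runs.
#'
#' @param source_length Source length in um (thickness `thickness` um).
#' @param geom A [ring_geometry()]; its focal radius sets the arc.
#' @param thickness Source thickness in um (default 5).
#' @param medium An [acoustic_medium()].
#' @param max_theta Largest arc angle sampled, radians (defaults to the outer
#'   aperture angle; pass `pi/2` to support NA-coverage sweeps up to NA = 1).
#' @param spacing Element spacing along the arc in mm.
#' @param dx,dt,pml Grid parameters.
#' @param tail Extra simulated path after the focal arrival, in mm.
#' @return A `detection_run`: the dense `pressure_traces`, the element table
#'   and the geometry.
#' @export
simulate_detection <- function(source_length, geom = ring_geometry(),
                               thickness = 5, medium = acoustic_medium(),
                               max_theta = NULL, spacing = 0.005,
                               dx = 0.005, dt = 0.001, pml = 20L,
                               tail = 0.15, smooth_source = FALSE) {
  stopifnot(inherits(geom, "ring_geometry"))
  R <- geom$focal_radius
  if (is.null(max_theta)) max_theta <- geom$theta_outer
  full <- ring_geometry(focal_radius = R, na = sin(max_theta))
  elements <- sample_elements(full, spacing = spacing)
  margin <- 0.12
  grid <- .grid_covering(
    c(min(elements$x) - margin, max(elements$x) + margin),
    c(min(elements$z) - margin, source_length / 2000 + margin),
    dx = dx, dt = dt, pml = pml)
  src <- make_line_source(source_length, thickness, grid, center = c(0, 0))
  tr <- propagate(src, medium, sensor_points(elements$x, elements$z),
                  t_end = (R + tail) / medium$sound_speed,
                  smooth_source = smooth_source)
  structure(list(traces = tr, elements = elements, geom = geom,
                 source_length = source_length, thickness = thickness,
                 medium = medium),
            class = "detection_run")
}

#' @export
print.detection_run <- function(x, ...) {
  cat(sprintf("<detection_run> %g um source, %d arc elements, R = %.3f mm\n",
              x$source_length, nrow(x$elements), x$geom$focal_radius))
  invisible(x)
}

# select element columns of a detection run for a given geometry
.element_subset <- function(run, theta_inner, theta_outer) {
  which(abs(run$elements$theta) >= theta_inner - 1e-12 &
          abs(run$elements$theta) <= theta_outer + 1e-12)
}

#' Aggregate a stored detection run for a given detector geometry
#'
#' @param run A [simulate_detection()] result.
#' @param geom A [ring_geometry()] sharing the run's focal radius.
#' @param band_limit Optional low-pass cut-off in MHz applied to the element
#'   traces before aggregation.
#' @return A `detector_signal`.
#' @export
aggregate_detector <- function(run, geom = run$geom, band_limit = NULL) {
  stopifnot(inherits(run, "detection_run"), inherits(geom, "ring_geometry"))
  if (abs(geom$focal_radius - run$geom$focal_radius) > 1e-9)
    .stop2("geometry focal radius does not match the stored run",
           "ringpam_parameter_error")
  cols <- .element_subset(run, geom$theta_inner, geom$theta_outer)
  if (length(cols) < 2)
    .stop2("fewer than 2 stored elements fall on the active arc; reduce the element spacing",
           "ringpam_parameter_error")
  tr <- run$traces
  if (!is.null(band_limit)) tr <- apply_band_limit(tr, band_limit)
  aggregate_elements(tr, columns = cols)
}
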