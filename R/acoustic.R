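#' Homogeneous acoustic medium with quadratic power-law absorption
#'
#' Water-like medium for the 2D wave solver.  Amplitude absorption follows
#' `alpha(f) = alpha0 * f^2`; the quadratic (thermoviscous) exponent carries
#' no dispersion correction, so it is implemented as an exact per-step
#' spectral amplitude filter.
#'
#' @param sound_speed Sound speed in mm/us (default 1.5, water).
#' @param alpha0 Absorption coefficient in dB/(MHz^2 cm) (default 0.0022,
#'   water).
#' @param power_law_exponent Must be 2; other exponents are not supported.
#' @param density Relative mass density (default 1).
#' @return An `acoustic_medium` object.
#' @export
acoustic_medium <- function(sound_speed = 1.5, alpha0 = 0.0022,
                            power_law_exponent = 2, density = 1) {
  if (sound_speed <= 0)
    .stop2("`sound_speed` must be positive", "ringpam_parameter_error")
  if (alpha0 < 0)
    .stop2("`alpha0` must be >= 0", "ringpam_parameter_error")
  if (power_law_exponent != 2)
    .stop2("only the quadratic power law (exponent 2) is supported",
           "ringpam_parameter_error")
  structure(list(sound_speed = sound_speed, alpha0 = alpha0,
                 power_law_exponent = 2, density = density),
            class = "acoustic_medium")
}

#' Regular 2D simulation grid
#'
#' Cartesian grid for the k-space solver.  x is the lateral coordinate and z
#' the detector axis (positive z pointing away from the detector, i.e. into
#' the medium); cell centres sit at `origin + (index - 1) * dx`.  The
#' supported maximum frequency is `c / (2 dx)` (150 MHz at the defaults).
#'
#' @param nx,nz Grid size in cells (including the absorbing boundary layer).
#' @param dx Spatial step in mm (default 0.005 = 5 um).
#' @param dt Time step in us (default 0.001 = 1 ns).
#' @param pml Thickness of the absorbing boundary layer in cells.
#' @param pml_alpha Peak PML absorption in nepers per grid point.
#' @param center Physical coordinates (mm) of the grid centre; used to place
#'   the grid when `origin` is not given.
#' @param origin Physical coordinates (mm) of cell (1, 1); overrides
#'   `center`.
#' @return A `sim_grid` object.
#' @export
sim_grid <- function(nx, nz, dx = 0.005, dt = 0.001, pml = 20L,
                     pml_alpha = 2, center = c(0, 0), origin = NULL) {
  nx <- as.integer(nx); nz <- as.integer(nz)
  if (dx <= 0 || dt <= 0)
    .stop2("`dx` and `dt` must be positive", "ringpam_parameter_error")
  if (is.null(origin))
    origin <- c(center[1] - (nx - 1) * dx / 2, center[2] - (nz - 1) * dx / 2)
  structure(list(nx = nx, nz = nz, dx = dx, dt = dt, pml = as.integer(pml),
                 pml_alpha = pml_alpha, origin = origin),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf(
    "<sim_grid> %d x %d cells, dx = %g mm, dt = %g us, PML %d cells\n",
    x$nx, x$nz, x$dx, x$dt, x$pml))
  cat(sprintf("  x: [%.3f, %.3f] mm, z: [%.3f, %.3f] mm\n",
              x$origin[1], x$origin[1] + (x$nx - 1) * x$dx,
              x$origin[2], x$origin[2] + (x$nz - 1) * x$dx))
  invisible(x)
}

# next FFT-friendly size (prime factors <= 7)
.good_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# grid covering physical ranges (mm), PML added outside
.grid_covering <- function(x_range, z_range, dx = 0.005, dt = 0.001,
                           pml = 20L, pml_alpha = 2) {
  nx <- .good_size(ceiling(diff(x_range) / dx) + 2L * pml + 2L)
  nz <- .good_size(ceiling(diff(z_range) / dx) + 2L * pml + 2L)
  # centre the requested region inside the enlarged grid
  cx <- mean(x_range); cz <- mean(z_range)
  sim_grid(nx, nz, dx = dx, dt = dt, pml = pml, pml_alpha = pml_alpha,
           center = c(cx, cz))
}

# physical (mm) -> fractional 0-based grid index
.grid_index <- function(grid, x, z) {
  cbind((x - grid$origin[1]) / grid$dx, (z - grid$origin[2]) / grid$dx)
}

.grid_usable <- function(grid, margin_cells = 2L) {
  m <- (grid$pml + margin_cells) * grid$dx
  list(x = c(grid$origin[1] + m,
             grid$origin[1] + (grid$nx - 1) * grid$dx - m),
       z = c(grid$origin[2] + m,
             grid$origin[2] + (grid$nz - 1) * grid$dx - m))
}

#' Rectangular vertical line source
#'
#' Initial-pressure patch representing an axially extended optoacoustic
#' source: a vertical rectangle of unit pressure, cell-snapped to the grid.
#' A thickness below one cell is represented by a single-cell column with
#' proportional amplitude scaling.
#'
#' @param length Vertical source extent in um (e.g. 20).
#' @param thickness Horizontal extent in um (default 5 = one cell at the
#'   default grid step).
#' @param grid A [sim_grid()].
#' @param center Source centre `c(x, z)` in mm.
#' @return An `initial_pressure`: the `p0` matrix plus its grid.
#' @export
make_line_source <- function(length, thickness = 5, grid,
                             center = c(0, 0)) {
  stopifnot(inherits(grid, "sim_grid"))
  if (length <= 0 || thickness <= 0)
    .stop2("source dimensions must be positive", "ringpam_geometry_error")
  dx_um <- grid$dx * 1000
  n_rows <- max(1L, as.integer(round(length / dx_um)))
  n_cols <- max(1L, as.integer(round(thickness / dx_um)))
  amp <- (thickness / dx_um) / n_cols * (length / dx_um) / n_rows
  ij <- .grid_index(grid, center[1], center[2])
  i0 <- round(ij[1, 1] + 1 - (n_cols - 1) / 2)
  j0 <- round(ij[1, 2] + 1 - (n_rows - 1) / 2)
  ii <- seq(i0, length.out = n_cols); jj <- seq(j0, length.out = n_rows)
  if (min(ii) <= grid$pml + 1 || max(ii) > grid$nx - grid$pml - 1 ||
      min(jj) <= grid$pml + 1 || max(jj) > grid$nz - grid$pml - 1)
    .stop2("source overlaps the absorbing boundary layer",
           "ringpam_geometry_error")
  p0 <- matrix(0, grid$nx, grid$nz)
  p0[ii, jj] <- amp
  structure(list(p0 = p0, grid = grid, center = center,
                 length = length, thickness = thickness),
            class = "initial_pressure")
}

#' Arbitrary initial-pressure field
#'
#' Wraps a user-supplied pressure matrix (e.g. a scaled absorbed-energy
#' slice, via a constant Grueneisen factor) as a solver source term.
#'
#' @param p0 Numeric matrix of size `nx` x `nz`.
#' @param grid The matching [sim_grid()].
#' @return An `initial_pressure`.
#' @export
initial_pressure <- function(p0, grid) {
  stopifnot(inherits(grid, "sim_grid"),
            nrow(p0) == grid$nx, ncol(p0) == grid$nz)
  if (!all(is.finite(p0)))
    .stop2("`p0` must be finite", "ringpam_parameter_error")
  structure(list(p0 = p0, grid = grid), class = "initial_pressure")
}

#' Sensor points for the wave solver
#'
#' @param x,z Sensor coordinates in mm.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A `sensor_set` tibble with attributes.
#' @export
sensor_points <- function(x, z, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  structure(tibble::tibble(x = x, z = z),
            class = c("sensor_set", "tbl_df", "tbl", "data.frame"),
            interpolation = interpolation)
}

#' Propagate an initial pressure distribution
#'
#' First-order coupled k-space pseudospectral update (pressure/velocity
#' split) with exact spectral derivatives, the k-space temporal correction
#' `sinc(c k dt / 2)`, a per-step spectral attenuation filter implementing
#' `alpha(f) = alpha0 f^2`, and a split-field absorbing boundary layer.
#' Pressure is recorded at the sensor points at every time step.
#'
#' @param p0 An `initial_pressure` (see [make_line_source()]).
#' @param medium An [acoustic_medium()].
#' @param sensors A [sensor_points()] set (or a two-column matrix of x, z in
#'   mm).
#' @param t_end Simulated duration in us (`nt = round(t_end / dt)` steps).
#' @param smooth_source Apply a separable Blackman window in k-space to the
#'   initial pressure.  Off by default: cell-snapped sources carry physical
#'   broadband content up to the grid-supported 150 MHz, and the exact
#'   k-space propagator needs no anti-ringing filter; enable it to emulate
#'   solvers that smooth their source terms.
#' @param record_energy Record total acoustic energy in the interior at each
#'   step (diagnostic).
#' @param u0 Optional list with `ux`, `uz` initial particle-velocity
#'   matrices, sampled on the staggered grid at `t = dt/2` (advanced use:
#'   travelling-wave initial conditions).
#' @return A `pressure_traces` object: `traces` matrix (time along rows),
#'   time axis, sensors, final pressure field and the grid.
#' @export
propagate <- function(p0, medium = acoustic_medium(), sensors, t_end,
                      smooth_source = FALSE, record_energy = FALSE,
                      u0 = NULL) {
  stopifnot(inherits(p0, "initial_pressure"),
            inherits(medium, "acoustic_medium"))
  grid <- p0$grid
  cfl <- medium$sound_speed * grid$dt / grid$dx
  if (cfl > 0.3 + 1e-12)
    .stop2(sprintf("CFL number %.3f exceeds 0.3; reduce dt or increase dx",
                   cfl), "ringpam_config_error")
  if (is.matrix(sensors)) sensors <- sensor_points(sensors[, 1], sensors[, 2])
  stopifnot(inherits(sensors, "sensor_set"))
  us <- .grid_usable(grid, 0L)
  if (any(sensors$x < us$x[1] | sensors$x > us$x[2] |
          sensors$z < us$z[1] | sensors$z > us$z[2]))
    .stop2("sensors must lie inside the non-PML region",
           "ringpam_geometry_error")
  ij <- .grid_index(grid, sensors$x, sensors$z)
  if (attr(sensors, "interpolation") == "nearest") ij <- round(ij)
  nt <- as.integer(round(t_end / grid$dt))
  alpha_np <- .alpha_db_to_np_mm(medium$alpha0)
  ux0 <- if (!is.null(u0)) u0$ux else NULL
  uz0 <- if (!is.null(u0)) u0$uz else NULL
  res <- .ks_propagate(p0$p0, grid$dx, grid$dt, nt, medium$sound_speed,
                       medium$density, alpha_np, grid$pml, grid$pml_alpha,
                       ij, smooth_source, record_energy, ux0, uz0)
  structure(list(traces = res$traces, dt = grid$dt,
                 t = seq_len(nt) * grid$dt, sensors = sensors,
                 p_final = res$p_final, energy = res$energy,
                 grid = grid, medium = medium),
            class = "pressure_traces")
}

#' @export
print.pressure_traces <- function(x, ...) {
  cat(sprintf("<pressure_traces> %d sensors x %d samples, dt = %g us\n",
              ncol(x$traces), nrow(x$traces), x$dt))
  invisible(x)
}

#' @export
tidy.pressure_traces <- function(x, ...) {
  ns <- ncol(x$traces)
  tibble::tibble(sensor = rep(seq_len(ns), each = nrow(x$traces)),
                 t = rep(x$t, times = ns),
                 pressure = as.vector(x$traces))
}

#' Angular radiation pattern of a vertical line source
#'
#' Peak-to-peak received amplitude on a semicircle of sensors centred on the
#' source, as a function of the angle from the source (z) axis.  An axially
#' extended source has a dipole-like pattern: a dip on axis and maxima
#' towards the perpendicular direction.
#'
#' @param length Source length in um.
#' @param radius Arc radius in mm.
#' @param n_angles Number of sensor angles across (-90, 90) degrees.
#' @param medium An [acoustic_medium()].
#' @param dx,dt,pml Grid parameters (see [sim_grid()]).
#' @param max_angle Largest |angle| in degrees (default 88 to keep sensors
#'   clear of the boundary layer).
#' @param smooth_source Passed to [propagate()]; smoothing band-limits a
#'   single-cell source, which is required for its pattern to be
#'   grid-isotropic (unsmoothed cell sources carry corner-of-k-space
#'   content that propagates anisotropically on any Cartesian grid).
#' @return A tibble with columns `angle` (degrees) and `amplitude`.
#' @export
directivity_of_line_source <- function(length, radius = 2.75, n_angles = 19,
                                       medium = acoustic_medium(),
                                       dx = 0.005, dt = 0.001, pml = 20L,
                                       max_angle = 88,
                                       smooth_source = FALSE) {
  if (radius < 10 * length / 1000)
    .stop2("arc radius must be much larger than the source length",
           "ringpam_geometry_error")
  ang <- seq(-max_angle, max_angle, length.out = n_angles) * pi / 180
  margin <- 0.12
  grid <- .grid_covering(c(-radius - margin, radius + margin),
                         c(-radius - margin, margin + length / 1000),
                         dx = dx, dt = dt, pml = pml)
  src <- make_line_source(length, grid = grid, center = c(0, 0))
  # snap sensors to cells: bilinear interpolation of near-Nyquist pulses
  # scallops the amplitude by up to ~10% depending on sub-cell alignment,
  # which would masquerade as angular structure
  sens <- sensor_points(radius * sin(ang), -radius * cos(ang),
                        interpolation = "nearest")
  tr <- propagate(src, medium, sens,
                  t_end = (radius + 0.1) / medium$sound_speed,
                  smooth_source = smooth_source)
  amp <- apply(tr$traces, 2, function(v) max(v) - min(v))
  tibble::tibble(angle = ang * 180 / pi, amplitude = amp)
}
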