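#' Extract an axial absorbed-energy profile
#'
#' Profile of absorbed energy along z, either on the beam axis (with a small
#' lateral averaging window for variance reduction, default 3 x 3 voxels) or
#' laterally integrated over the whole slice.
#'
#' @param grid An `absorbed_energy_grid` from [trace_photons()].
#' @param x,y Lateral position of the profile line in um; defaults to the
#'   beam focus.
#' @param mode `"on_axis"` (default) or `"laterally_integrated"`.
#' @param lateral_halfwidth Half-width, in voxels, of the on-axis averaging
#'   window (1 gives 3 x 3 voxels).
#' @return An `axial_profile`: tibble with columns `z` (um) and `value`.
#' @export
extract_axial_profile <- function(grid, x = NULL, y = NULL,
                                  mode = c("on_axis", "laterally_integrated"),
                                  lateral_halfwidth = 1L) {
  stopifnot(inherits(grid, "absorbed_energy_grid"))
  mode <- match.arg(mode)
  dims <- dim(grid$values); pitch <- grid$pitch
  if (is.null(x)) x <- grid$focus[1]
  if (is.null(y)) y <- grid$focus[2]
  i0 <- as.integer(ceiling(x / pitch)); j0 <- as.integer(ceiling(y / pitch))
  if (i0 < 1 || i0 > dims[1] || j0 < 1 || j0 > dims[2])
    .stop2("profile line lies outside the grid", "ringpam_geometry_error")
  if (mode == "on_axis") {
    h <- as.integer(lateral_halfwidth)
    ii <- max(1, i0 - h):min(dims[1], i0 + h)
    jj <- max(1, j0 - h):min(dims[2], j0 + h)
    v <- apply(grid$values[ii, jj, , drop = FALSE], 3, mean)
  } else {
    v <- apply(grid$values, 3, sum)
  }
  z <- (seq_len(dims[3]) - 0.5) * pitch
  structure(tibble::tibble(z = z, value = v),
            class = c("axial_profile", "tbl_df", "tbl", "data.frame"),
            pitch = pitch, mode = mode)
}

#' Full width at half maximum of a peaked profile
#'
#' Linear interpolation between the samples bracketing the half-maximum level
#' on both sides of the global maximum.  Errors (condition class
#' `ringpam_open_profile`) when the profile never crosses the half level on
#' one side, or has no proper maximum (e.g. a uniform field).
#'
#' @param x An `axial_profile`, or a numeric vector of sample positions.
#' @param ... Passed on to methods.
#' @return The width, in the units of the position axis.
#' @examples
#' z <- seq(-50, 50, by = 1)
#' fwhm(z, exp(-z^2 / (2 * 10^2)))  # 2.3548 * sigma
#' @export
fwhm <- function(x, ...) UseMethod("fwhm")

#' @rdname fwhm
#' @param value Profile samples (for the default method).
#' @param level Relative level at which the width is measured (default 0.5).
#' @export
fwhm.default <- function(x, value, level = 0.5, ...) {
  z <- as.numeric(x); v <- as.numeric(value)
  stopifnot(length(z) == length(v), length(z) >= 3)
  if (is.unsorted(z, strictly = TRUE))
    .stop2("positions must be strictly increasing", "ringpam_parameter_error")
  vmax <- max(v)
  if (!is.finite(vmax) || vmax <= 0 || vmax <= min(v) + 1e-12 * abs(vmax))
    .stop2("profile has no proper maximum; FWHM undefined",
           "ringpam_open_profile")
  imax <- which.max(v)
  half <- level * vmax
  # left crossing
  left <- NA_real_
  for (i in seq(imax, 2)) {
    if (v[i - 1] < half && v[i] >= half) {
      left <- z[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) *
        (z[i] - z[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(imax, length(v) - 1)) {
    if (v[i] >= half && v[i + 1] < half) {
      right <- z[i] + (v[i] - half) / (v[i] - v[i + 1]) * (z[i + 1] - z[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    .stop2("half-maximum level is never crossed on one side (open profile)",
           "ringpam_open_profile")
  right - left
}

#' @rdname fwhm
#' @export
fwhm.axial_profile <- function(x, level = 0.5, ...) {
  fwhm.default(x$z, x$value, level = level)
}

#' @rdname fwhm
#' @export
fwhm.reception_field <- function(x, level = 0.5, ...) {
  fwhm.default(x$field$z, x$field$amplitude, level = level)
}

#' @export
glance.axial_profile <- function(x, ...) {
  fw <- tryCatch(fwhm(x), ringpam_open_profile = function(e) NA_real_)
  tibble::tibble(fwhm = fw, z_peak = x$z[which.max(x$value)],
                 mode = attr(x, "mode") %||% NA_character_)
}

#' @export
tidy.axial_profile <- function(x, ...) {
  tibble::tibble(z = x$z, value = x$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Absorbed-energy FWHM versus vessel diameter
#'
#' For each diameter, builds the two-layer phantom, focuses the beam at the
#' vessel centre, runs the photon Monte-Carlo and measures the FWHM of the
#' on-axis absorbed-energy depth profile.
#'
#' @param diameters Vessel diameters in um.
#' @param depth Depth of the vessel top below the tissue surface (um).
#' @param beam A [beam_spec()].
#' @param budget A [photon_budget()]; each diameter uses `seed + index - 1`.
#' @param dims,water_depth Passed to [build_vessel_phantom()]; `dims = NULL`
#'   sizes the grid automatically to the vessel.
#' @param ... Passed to [extract_axial_profile()].
#' @return A tibble with columns `diameter`, `fwhm` and `n_photons`.
#' @export
vessel_fwhm_study <- function(diameters, depth = 100, beam = beam_spec(),
                              budget = photon_budget(), dims = NULL,
                              water_depth = 50, ...) {
  if (any(diameters <= 0))
    .stop2("diameters must be positive", "ringpam_parameter_error")
  rows <- lapply(seq_along(diameters), function(i) {
    d <- diameters[i]
    dm <- dims
    if (is.null(dm)) {
      nz <- as.integer(ceiling((water_depth + depth + d + 80) / 1) + 40)
      nl <- as.integer(max(160, 2 * ceiling(d / 2 + 30)))
      dm <- c(nl, nl, nz)
    }
    ph <- build_vessel_phantom(vessel_spec(d, depth_of_top = depth),
                               dims = dm, water_depth = water_depth)
    bud <- budget; bud$seed <- budget$seed + i - 1
    g <- trace_photons(ph, beam, bud)
    pr <- extract_axial_profile(g, ...)
    tibble::tibble(diameter = d, fwhm = fwhm(pr),
                   n_photons = budget$n_photons)
  })
  dplyr::bind_rows(rows)
}
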