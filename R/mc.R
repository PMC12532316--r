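#' Focused Gaussian illumination beam
#'
#' Low-NA Gaussian beam focused at a point inside the phantom.  The launch
#' model samples, independently for every photon, a waist crossing point
#' (Gaussian, 1/e^2 intensity radius `w0 = lambda / (pi * NA)`) and a
#' propagation slope (Gaussian, 1/e^2 half-angle `NA / n` in the medium), and
#' aims the photon through the sampled waist point.  This reproduces the
#' Gaussian-beam caustic `w(z)^2 = w0^2 + (theta z)^2` around the focus.
#'
#' @param wavelength Optical wavelength in nm (default 532).
#' @param na Numerical aperture of the focusing lens (0 < NA < 1).
#' @param focus Focus position `c(x, y, z)` in um, z measured downward from
#'   the top of the grid.  `NULL` defers to the caller (e.g.
#'   [trace_photons()] centres x/y on the grid).
#' @param n_medium Refractive index used to convert NA to the in-medium
#'   divergence angle (default 1.33, water).
#' @return A `beam_spec` object.
#' @examples
#' beam_spec()$w0  # 1/e^2 waist radius in um
#' @export
beam_spec <- function(wavelength = 532, na = 0.06, focus = NULL,
                      n_medium = 1.33) {
  if (!is.numeric(na) || na <= 0 || na >= 1)
    .stop2("`na` must be in (0, 1)", "ringpam_parameter_error")
  if (!is.numeric(wavelength) || wavelength <= 0)
    .stop2("`wavelength` must be positive (nm)", "ringpam_parameter_error")
  w0 <- (wavelength * 1e-3) / (pi * na)          # um, 1/e^2 radius
  theta <- asin(na / n_medium)                   # rad, in-medium half-angle
  structure(list(wavelength = wavelength, na = na, focus = focus,
                 n_medium = n_medium, w0 = w0, theta = theta),
            class = "beam_spec")
}

#' Photon budget and random stream for a Monte-Carlo run
#'
#' @param n_photons Number of photons to launch (>= 1).
#' @param seed Integer master seed; each photon derives its own counter-based
#'   random stream from it, so runs are bit-reproducible.
#' @param roulette_threshold Weight below which Russian roulette is played
#'   (0 disables roulette).
#' @param roulette_survival Survival probability of the roulette.
#' @return A `photon_budget` object.
#' @export
photon_budget <- function(n_photons = 1e6, seed = 1L,
                          roulette_threshold = 1e-4,
                          roulette_survival = 0.1) {
  if (!is.numeric(n_photons) || n_photons < 1)
    .stop2("`n_photons` must be >= 1", "ringpam_parameter_error")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    .stop2("`seed` must be a single integer", "ringpam_parameter_error")
  if (roulette_threshold > 0 &&
      (roulette_survival <= 0 || roulette_survival >= 1))
    .stop2("`roulette_survival` must be in (0, 1)", "ringpam_parameter_error")
  structure(list(n_photons = as.double(n_photons), seed = as.double(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "photon_budget")
}

#' Monte-Carlo photon transport through a voxel phantom
#'
#' Weighted-photon random walk: exponential free paths with
#' `mu_t = mu_a + mu_s`, deposition of `w * mu_a / mu_t` at every interaction
#' site, Henyey-Greenstein deflection, Russian roulette.  Returns the 3D
#' absorbed-energy density (deposited photon weight per voxel, relative
#' units).
#'
#' @param phantom A [build_vessel_phantom()] result (or any `voxel_phantom`).
#' @param beam A [beam_spec()]; if its `focus` is `NULL` the beam is centred
#'   laterally and focused at the vessel centre.
#' @param budget A [photon_budget()].
#' @return An `absorbed_energy_grid`: the `values` array plus the
#'   launched/absorbed/escaped weight bookkeeping.
#' @examples
#' ph <- build_vessel_phantom(vessel_spec(20), dims = c(60, 40, 220))
#' g <- trace_photons(ph, beam_spec(), photon_budget(2e4, seed = 7))
#' glance(g)
#' @export
trace_photons <- function(phantom, beam = beam_spec(),
                          budget = photon_budget()) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(beam, "beam_spec"),
            inherits(budget, "photon_budget"))
  dims <- phantom$dims; pitch <- phantom$pitch
  focus <- beam$focus
  if (is.null(focus)) {
    focus <- c(dims[1] * pitch / 2, dims[2] * pitch / 2,
               phantom$water_depth + phantom$vessel$depth_of_top +
                 phantom$vessel$diameter / 2)
  }
  if (focus[3] <= 0 || focus[3] >= dims[3] * pitch ||
      focus[1] <= 0 || focus[1] >= dims[1] * pitch ||
      focus[2] <= 0 || focus[2] >= dims[2] * pitch)
    .stop2("beam focus lies outside the grid", "ringpam_geometry_error")

  props <- as.matrix(phantom$properties[, c("mu_a", "mu_s", "g")])
  props[, 1:2] <- props[, 1:2] * 1e-4              # 1/cm -> 1/um
  bm <- c(focus, beam$w0 / 2, beam$theta / 2)      # sigmas of the 1/e^2 defs
  res <- .mc_trace(as.integer(phantom$label) - 1L, dims, pitch, props,
                   budget$n_photons, budget$seed, bm,
                   budget$roulette_threshold, budget$roulette_survival)
  structure(list(values = res$absorbed, pitch = pitch,
                 launched = res$launched, absorbed = res$absorbed_total,
                 escaped = res$escaped,
                 residual = res$launched - res$absorbed_total - res$escaped,
                 focus = focus, beam = beam, phantom_dims = dims,
                 water_depth = phantom$water_depth),
            class = "absorbed_energy_grid")
}

#' @export
print.absorbed_energy_grid <- function(x, ...) {
  cat(sprintf(
    "<absorbed_energy_grid> %s voxels at %g um; absorbed %.1f%% of %g photons\n",
    paste(x$phantom_dims, collapse = " x "), x$pitch,
    100 * x$absorbed / x$launched, x$launched))
  invisible(x)
}

#' @rdname trace_photons
#' @param x An `absorbed_energy_grid`.
#' @param ... Unused.
#' @export
glance.absorbed_energy_grid <- function(x, ...) {
  tibble::tibble(launched = x$launched, absorbed = x$absorbed,
                 escaped = x$escaped, residual = x$residual,
                 absorbed_fraction = x$absorbed / x$launched)
}

#' Henyey-Greenstein deflection sampler (diagnostic)
#'
#' Draws deflection cosines from the Henyey-Greenstein phase function with
#' the same sampler used inside the photon random walk, for statistical
#' verification (the empirical mean cosine must approach `g`).
#'
#' @param n Number of draws.
#' @param g Anisotropy factor.
#' @param seed Integer seed.
#' @return Numeric vector of `cos(theta)` draws.
#' @export
sample_hg_cosines <- function(n, g, seed = 1L) {
  .mc_hg_sample(as.integer(n), g, as.double(seed))
}

#' Beam launch sampler (diagnostic)
#'
#' Samples photon positions and directions of the focused Gaussian launch
#' model at a given z plane, for verification of the waist statistics and
#' angular spread.
#'
#' @param n Number of photons.
#' @param beam A [beam_spec()] with a non-`NULL` focus.
#' @param z_plane Plane (um, downward) at which positions are reported.
#' @param seed Integer seed.
#' @return A tibble with columns x, y (um) and the direction cosines.
#' @export
sample_beam <- function(n, beam, z_plane, seed = 1L) {
  stopifnot(inherits(beam, "beam_spec"), !is.null(beam$focus))
  bm <- c(beam$focus, beam$w0 / 2, beam$theta / 2)
  m <- .mc_beam_sample(as.integer(n), bm, z_plane, as.double(seed))
  tibble::tibble(x = m[, 1], y = m[, 2], ux = m[, 3], uy = m[, 4],
                 uz = m[, 5])
}
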