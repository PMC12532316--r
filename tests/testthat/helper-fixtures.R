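# Shared fixtures. Expensive full-scale runs are computed lazily, once per
# session, and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# full-scale detection run (production geometry) for a given source length
detection_run_full <- function(length_um) {
  fixture(paste0("det_", length_um), function() {
    simulate_detection(length_um, geom = ring_geometry())
  })
}

# a small, fast phantom + MC result reused by profile/extraction tests
mc_small <- function() {
  fixture("mc_small", function() {
    ph <- build_vessel_phantom(vessel_spec(20), dims = c(80, 80, 240))
    trace_photons(ph, beam_spec(), photon_budget(5e4, seed = 42))
  })
}

# scaled-down detector geometry for sweep/reception properties:
# same angular layout as the production detector at a 0.7 mm focal radius
geom_scaled <- function(ring = FALSE) {
  R <- 0.7
  D <- 2 * R * sin(ring_geometry()$theta_outer)
  WD <- sqrt(R^2 - (D / 2)^2)
  if (ring) ring_geometry(D, WD, ring_width = 0.03)
  else ring_geometry(D, WD)
}

detection_run_scaled <- function(length_um = 20) {
  fixture(paste0("det_scaled_", length_um), function() {
    simulate_detection(length_um, geom = geom_scaled(), tail = 0.1)
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
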