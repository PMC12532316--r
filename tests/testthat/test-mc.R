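# Monte-Carlo transport: conservation, closed-form limits, samplers.

.slab_phantom <- function(mu_a, mu_s = 0, g = 0, dims = c(40, 40, 300)) {
  p <- optical_properties(mu_a, mu_s, g)
  build_vessel_phantom(vessel_spec(10, depth_of_top = 5, properties = p),
                       tissue = p, water = p, water_depth = 0, dims = dims)
}

test_that("weight is conserved exactly when roulette is disabled", {
  ph <- .slab_phantom(80, mu_s = 120, g = 0.8)
  g <- trace_photons(ph, beam_spec(focus = c(20, 20, 50)),
                     photon_budget(2e4, seed = 5, roulette_threshold = 0))
  gl <- glance(g)
  expect_lt(abs(gl$residual) / gl$launched, 1e-9)
  expect_true(all(g$values >= 0))
  expect_lte(gl$absorbed, gl$launched)
})

test_that("roulette keeps the absorbed fraction unbiased", {
  ph <- .slab_phantom(80, mu_s = 120, g = 0.8)
  beam <- beam_spec(focus = c(20, 20, 50))
  g0 <- trace_photons(ph, beam, photon_budget(3e4, seed = 5,
                                              roulette_threshold = 0))
  g1 <- trace_photons(ph, beam, photon_budget(3e4, seed = 6))
  expect_rel(glance(g1)$absorbed_fraction, glance(g0)$absorbed_fraction,
             0.02)
})

test_that("collimated beam in a pure absorber follows Beer-Lambert", {
  mu_a <- 100                                   # 1/cm
  ph <- .slab_phantom(mu_a)
  g <- trace_photons(ph, beam_spec(focus = c(20, 20, 1)),
                     photon_budget(5e4, seed = 2, roulette_threshold = 0))
  gl <- glance(g)
  # absorbed fraction: closed form for the slab
  L_cm <- 300 * 1e-4
  expect_rel(gl$absorbed_fraction, 1 - exp(-mu_a * L_cm), 0.01)
  # depth-resolved deposition ~ exp(-mu_a z)
  prof <- extract_axial_profile(g, mode = "laterally_integrated")
  sl <- coef(lm(log(value) ~ z, data = prof[10:250, ]))[2]
  expect_rel(sl, -mu_a * 1e-4, 0.03)
})

test_that("Henyey-Greenstein sampler reproduces the mean cosine", {
  for (g in c(0, 0.5, 0.9, 0.98)) {
    cosines <- sample_hg_cosines(1e6, g, seed = 3)
    se <- sd(cosines) / sqrt(length(cosines))
    expect_lt(abs(mean(cosines) - g), 3 * se + 1e-6)
  }
})

test_that("beam launch statistics match the Gaussian-beam caustic", {
  b <- beam_spec(focus = c(0, 0, 200))
  at_focus <- sample_beam(2e5, b, 200, seed = 4)
  # radial marginal Gaussian with sigma = w0/2 at the waist
  expect_rel(sd(at_focus$x), b$w0 / 2, 0.02)
  expect_lt(abs(mean(at_focus$x)), 0.05)
  # Kolmogorov-ish normality check on standardized positions
  ks <- suppressWarnings(stats::ks.test(at_focus$x / sd(at_focus$x),
                                        "pnorm"))
  expect_gt(ks$p.value, 1e-4)
  # angular spread consistent with NA: sigma_theta = asin(NA/n)/2
  slopes <- at_focus$ux / at_focus$uz
  expect_rel(sd(slopes), asin(b$na / b$n_medium) / 2, 0.02)
  # width one Rayleigh range from focus grows by sqrt(2)
  zr <- pi * b$w0^2 * b$n_medium / (b$wavelength * 1e-3)
  away <- sample_beam(2e5, b, 200 + zr, seed = 4)
  expect_rel(sd(away$x), b$w0 / 2 * sqrt(2), 0.05)
})

test_that("runs are bit-reproducible for a fixed seed", {
  ph <- .slab_phantom(50, mu_s = 100, g = 0.9, dims = c(30, 30, 100))
  b <- beam_spec(focus = c(15, 15, 30))
  g1 <- trace_photons(ph, b, photon_budget(5e3, seed = 99))
  g2 <- trace_photons(ph, b, photon_budget(5e3, seed = 99))
  expect_identical(g1$values, g2$values)
  g3 <- trace_photons(ph, b, photon_budget(5e3, seed = 100))
  expect_false(identical(g1$values, g3$values))
})

test_that("invalid parameters are rejected", {
  expect_error(photon_budget(0), class = "ringpam_parameter_error")
  expect_error(photon_budget(10, roulette_survival = 1.5),
               class = "ringpam_parameter_error")
  expect_error(optical_properties(-1, 0, 0),
               class = "ringpam_parameter_error")
  expect_error(optical_properties(1, 0, 1.2),
               class = "ringpam_parameter_error")
  ph <- .slab_phantom(50, dims = c(30, 30, 100))
  expect_error(trace_photons(ph, beam_spec(focus = c(15, 15, 500)),
                             photon_budget(10)),
               class = "ringpam_geometry_error")
})

test_that("absorbed-energy FWHM grows with vessel diameter", {
  tab <- vessel_fwhm_study(c(20, 50), depth = 100,
                           budget = photon_budget(1.5e5, seed = 21))
  expect_true(all(diff(tab$fwhm) > 0))
  # 20 um vessel: profile truncated by the vessel, near its diameter
  expect_lt(abs(tab$fwhm[1] - 20), 3)
})

test_that("doubling the photon budget leaves the FWHM stable", {
  run_fwhm <- function(n, seed) {
    ph <- build_vessel_phantom(vessel_spec(50), dims = c(160, 160, 320))
    g <- trace_photons(ph, beam_spec(), photon_budget(n, seed = seed))
    fwhm(extract_axial_profile(g))
  }
  f1 <- run_fwhm(1e5, 31)
  f2 <- run_fwhm(2e5, 32)
  expect_lt(abs(f1 - f2) / f2, 0.10)
})
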