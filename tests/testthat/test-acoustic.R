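# k-space solver: exactness, spreading, attenuation, boundaries.

test_that("line sources are cell-snapped with the right extent", {
  g <- sim_grid(128, 128)
  s20 <- make_line_source(20, 5, g)
  expect_equal(sum(s20$p0 > 0), 4)          # 4 x 1 cells of unit p0
  expect_equal(max(s20$p0), 1)
  s50 <- make_line_source(50, 5, g)
  expect_equal(sum(s50$p0 > 0), 10)
  expect_equal(sum(s50$p0) / sum(s20$p0), 2.5)
  # sub-cell thickness becomes an amplitude scale
  s_half <- make_line_source(20, 2.5, g)
  expect_equal(max(s_half$p0), 0.5)
  expect_error(make_line_source(20, 5, g, center = c(0.31, 0)),
               class = "ringpam_geometry_error")
})

test_that("a travelling plane wave is advected exactly", {
  # periodic domain (no PML), travelling-wave initial conditions; after
  # nt steps with c dt nt = 255 dx the field is the initial one shifted by
  # 255 cells - the sinc-corrected scheme is exact for homogeneous media
  nx <- 512; nz <- 4; dxg <- 0.005; c0 <- 1.5; dtg <- 0.001
  g <- sim_grid(nx, nz, dx = dxg, dt = dtg, pml = 0, origin = c(0, 0))
  xc <- (seq_len(nx) - 1) * dxg
  f <- function(x) {
    x <- (x - 1.28) %% (nx * dxg)
    x[x > nx * dxg / 2] <- x[x > nx * dxg / 2] - nx * dxg
    exp(-x^2 / (2 * 0.05^2))
  }
  p0 <- matrix(f(xc), nx, nz)
  ux0 <- matrix(f(xc + dxg / 2 - c0 * dtg / 2), nx, nz)  # staggered u = p/(rho c)
  uz0 <- matrix(0, nx, nz)
  src <- initial_pressure(p0, g)
  nt <- 850                                  # shift = 0.3 * 850 = 255 cells
  tr <- propagate(src, acoustic_medium(alpha0 = 0),
                  sensor_points(0.5, 0.01), t_end = nt * dtg,
                  smooth_source = FALSE,
                  u0 = list(ux = ux0 / (1 * c0), uz = uz0))
  expected <- matrix(f(xc - 255 * dxg), nx, nz)
  expect_lt(max(abs(tr$p_final - expected)), 1e-9)
})

test_that("2D point source spreads as 1/sqrt(r) in the far field", {
  g <- sim_grid(480, 480)
  src <- make_line_source(5, 5, g)
  tr <- propagate(src, acoustic_medium(alpha0 = 0),
                  sensor_points(c(0.4, 0.9), c(0, 0)), t_end = 0.75)
  a <- apply(tr$traces, 2, function(v) max(abs(v)))
  expect_rel(a[1] / a[2], sqrt(0.9 / 0.4), 0.05)
})

test_that("quadratic power-law attenuation matches the closed form", {
  # 50 MHz packet over 1 mm: 0.0022 * 50^2 * 0.1 = 0.55 dB
  nz <- 2048; nx <- 8
  g <- sim_grid(nx, nz, pml = 0, origin = c(0, 0))
  z <- (seq_len(nz) - 1) * g$dx
  pkt <- sin(2 * pi * (50 / 1.5) * (z - 1)) * exp(-(z - 1)^2 / (2 * 0.06^2))
  src <- initial_pressure(matrix(rep(pkt, each = nx), nx, nz), g)
  tr <- propagate(src, acoustic_medium(alpha0 = 0.0022),
                  sensor_points(c(0.02, 0.02), c(2, 3)), t_end = 1.6,
                  smooth_source = FALSE)
  nt <- nrow(tr$traces)
  f <- (seq_len(nt) - 1) / (nt * tr$dt)
  i50 <- which.min(abs(f - 50))
  ratio <- Mod(fft(tr$traces[, 2]))[i50] / Mod(fft(tr$traces[, 1]))[i50]
  expect_rel(-20 * log10(ratio), 0.55, 0.05)
})

test_that("attenuated spectral ratio follows exp(-alpha(f) dr) per bin", {
  nz <- 2048; nx <- 8
  g <- sim_grid(nx, nz, pml = 0, origin = c(0, 0))
  z <- (seq_len(nz) - 1) * g$dx
  # broadband pulse
  pkt <- exp(-(z - 1)^2 / (2 * 0.01^2))
  src <- initial_pressure(matrix(rep(pkt, each = nx), nx, nz), g)
  tr <- propagate(src, acoustic_medium(alpha0 = 0.0022),
                  sensor_points(c(0.02, 0.02), c(2, 3)), t_end = 1.6,
                  smooth_source = FALSE)
  nt <- nrow(tr$traces)
  f <- (seq_len(nt) - 1) / (nt * tr$dt)
  s1 <- Mod(fft(tr$traces[, 1])); s2 <- Mod(fft(tr$traces[, 2]))
  band <- which(f > 5 & f < 60 & s1 > max(s1) / 10)   # -20 dB band
  measured_db <- -20 * log10(s2[band] / s1[band])
  expected_db <- 0.0022 * f[band]^2 * 0.1
  expect_lt(max(abs(measured_db - expected_db) / expected_db), 0.05)
})

test_that("lossless homogeneous run conserves acoustic energy", {
  g <- sim_grid(360, 360)
  src <- make_line_source(40, 20, g)
  tr <- propagate(src, acoustic_medium(alpha0 = 0),
                  sensor_points(0.2, 0), t_end = 0.25,
                  record_energy = TRUE)
  e <- tr$energy[20:250]                    # after source release settles
  expect_lt((max(e) - min(e)) / max(e), 1e-3)
})

test_that("extending t_end does not alter already-recorded samples", {
  g <- sim_grid(240, 240)
  src <- make_line_source(20, 5, g)
  s <- sensor_points(c(0.15, -0.2), c(0.1, 0.05))
  t1 <- propagate(src, acoustic_medium(), s, t_end = 0.2)
  t2 <- propagate(src, acoustic_medium(), s, t_end = 0.3)
  expect_equal(t2$traces[seq_len(nrow(t1$traces)), ], t1$traces,
               tolerance = 1e-12)
})

test_that("absorbing boundary layer reflects below -40 dB", {
  # point pulse from the centre; after the direct arrival passes the
  # sensor, everything that comes back is boundary reflection
  g <- sim_grid(360, 360, pml = 20, center = c(0, 0))   # walls at +-0.8 mm
  src <- make_line_source(5, 5, g, center = c(0, 0))
  tr <- propagate(src, acoustic_medium(alpha0 = 0),
                  sensor_points(0, 0.5), t_end = 1.6,
                  smooth_source = TRUE)
  v <- tr$traces[, 1]
  t <- tr$t
  direct <- max(abs(v[t < 0.5]))            # arrival at 0.33 us
  late <- max(abs(v[t > 0.6]))              # earliest reflection ~0.73 us
  expect_lt(20 * log10(late / direct), -40)
})

test_that("stability and geometry violations raise configuration errors", {
  g <- sim_grid(64, 64, dt = 0.005)          # CFL = 1.5
  src <- initial_pressure(matrix(0, 64, 64), g)
  expect_error(propagate(src, acoustic_medium(), sensor_points(0, 0),
                         t_end = 0.01),
               class = "ringpam_config_error")
  g2 <- sim_grid(64, 64)
  src2 <- make_line_source(20, 5, g2)
  expect_error(propagate(src2, acoustic_medium(),
                         sensor_points(0.158, 0), t_end = 0.01),
               class = "ringpam_geometry_error")
  expect_error(acoustic_medium(power_law_exponent = 1.5),
               class = "ringpam_parameter_error")
})

test_that("line-source directivity has an axial dip and off-axis maxima", {
  d <- directivity_of_line_source(40, radius = 0.5, n_angles = 11,
                                  dx = 0.005)
  on_axis <- d$amplitude[abs(d$angle) < 10]
  edge <- d$amplitude[abs(d$angle) > 70]
  expect_gt(min(edge), max(on_axis))
  # mirror symmetry
  expect_equal(d$amplitude, rev(d$amplitude), tolerance = 0.02)
})

test_that("a band-limited single-cell source radiates almost isotropically", {
  d <- directivity_of_line_source(5, radius = 0.5, n_angles = 11,
                                  smooth_source = TRUE)
  expect_lt(max(d$amplitude) / min(d$amplitude), 1.1)
})
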