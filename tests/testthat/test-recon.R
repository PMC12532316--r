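# A-scan processing chain and closed-form estimators.

test_that("time-to-depth transform and its inverse round-trip", {
  expect_equal(time_to_depth(2.3 / 1.5), 0)
  # an arrival at the focal radius maps close to the working distance
  expect_equal(time_to_depth(2.75 / 1.5), sqrt(2.75^2 - 2.3^2),
               tolerance = 1e-12)
  expect_equal(sqrt(2.75^2 - 2.3^2), 1.5075, tolerance = 1e-4)
  expect_error(time_to_depth(1.0), class = "ringpam_domain_error")
  z <- seq(0.01, 3, length.out = 50)
  expect_equal(time_to_depth(depth_to_time(z)), z, tolerance = 1e-12)
  t <- depth_to_time(z)
  expect_true(all(diff(time_to_depth(t)) > 0))     # strictly increasing
})

test_that("envelope of standard signals behaves like the analytic signal", {
  t <- seq(0, 10, by = 1e-3)
  s <- 0.7 * sin(2 * pi * 5 * t)
  e <- envelope(s)
  core <- e[500:9500]
  expect_lt(max(abs(core - 0.7)) / 0.7, 0.01)
  expect_true(all(e >= abs(s) - 1e-9))
  expect_equal(envelope(numeric(128)), numeric(128))
  # gated 11 MHz tone burst (dt = 1 ns): envelope peak = burst amplitude
  tt <- seq_len(4000) * 1e-3
  burst <- sin(2 * pi * 11 * tt) * exp(-(tt - 2)^2 / (2 * 0.2^2))
  expect_rel(max(envelope(burst)), 1, 0.02)
})

test_that("zero-phase low-pass suppresses the stop band and not DC", {
  set.seed(1)
  x <- rnorm(8192)
  y <- lowpass(x, cutoff = 30, dt = 0.001)
  f <- (seq_along(x) - 1) / (length(x) * 0.001)
  px <- Mod(fft(x))^2; py <- Mod(fft(y))^2
  stop_band <- f > 60 & f < 450
  expect_gt(10 * log10(sum(px[stop_band]) / sum(py[stop_band])), 40)
  dc <- rep(3, 1024)
  expect_equal(lowpass(dc, 30, 0.001), dc, tolerance = 1e-6)
  # near-idempotence on a band-limited pulse
  tt <- seq_len(2048) * 1e-3
  pulse <- sin(2 * pi * 10 * tt) * exp(-(tt - 1)^2 / (2 * 0.05^2))
  once <- lowpass(pulse, 30, 0.001)
  twice <- lowpass(once, 30, 0.001)
  expect_lt(max(abs(twice - once)) / max(abs(once)), 0.01)
  expect_error(lowpass(x, cutoff = 600, dt = 0.001),
               class = "ringpam_parameter_error")
  # energy never increases
  expect_lte(sum(y^2), sum(x^2))
})

test_that("maximum intensity projection handles masks and constants", {
  v <- array(0, c(5, 4, 6))
  v[2, 3, 4] <- 7
  img <- mip(v)
  expect_equal(img[2, 3], 7)
  expect_equal(sum(img), 7)
  vc <- array(2, c(3, 3, 3))
  expect_true(all(mip(vc) == 2))
  v[2, 3, ] <- NA
  expect_true(is.na(mip(v)[2, 3]))
  # axis permutation of an isotropic volume commutes with the projection
  set.seed(2)
  iso <- array(abs(rnorm(4^3)), c(4, 4, 4))
  expect_equal(mip(iso, 3), t(mip(aperm(iso, c(2, 1, 3)), 3)))
})

test_that("spectrum statistics recover peak and -20 dB width", {
  dt <- 0.001
  tt <- seq_len(8192) * dt
  burst <- sin(2 * pi * 11 * tt) * exp(-(tt - 4)^2 / (2 * 0.5^2))
  st <- spectrum_stats(burst, dt)
  expect_lt(abs(st$peak_frequency - 11), 1 / (8192 * dt) + 0.01)
  # Gaussian-enveloped pulse |S(f)| ~ exp(-2 pi^2 sigma_t^2 (f - f0)^2):
  # -20 dB full width = 2 sqrt(ln 10 / (2 pi^2 sigma_t^2))
  sigma_t <- 0.1
  pulse <- sin(2 * pi * 25 * tt) * exp(-(tt - 4)^2 / (2 * sigma_t^2))
  st2 <- spectrum_stats(pulse, dt)
  expect_rel(st2$width_minus20db,
             2 * sqrt(log(10) / (2 * pi^2 * sigma_t^2)), 0.02)
  # white noise marks the band as degenerate
  set.seed(3)
  stn <- spectrum_stats(rnorm(4096), dt)
  expect_true(stn$degenerate)
  expect_error(spectrum_stats(numeric(10), dt),
               class = "ringpam_parameter_error")
})

test_that("closed-form resolution estimators match the printed values", {
  expect_equal(axial_resolution(28, 1.5), 47.14, tolerance = 1e-3)
  expect_equal(axial_resolution(56, 1.5), axial_resolution(28, 1.5) / 2)
  ra50 <- 0.88 * 1.5 / 0.05 / 1000   # delta_f that gives 50 um
  expect_equal(axial_resolution(0.88 * 1.5 / 0.05), 50)
  expect_equal(focal_waist(532, 0.06), 4.433, tolerance = 1e-3)
  expect_equal(focal_waist(532, 0.12), focal_waist(532, 0.06) / 2)
  expect_equal(focal_waist(600, 0.5), 0.6)
  expect_error(axial_resolution(0), class = "ringpam_parameter_error")
  expect_error(focal_waist(532, 0), class = "ringpam_parameter_error")
})

test_that("lateral profile width matches a known PSF", {
  x <- seq_len(101)
  sigma <- 4
  b <- matrix(0, 101, 3)
  b[, 2] <- exp(-(x - 51)^2 / (2 * sigma^2))
  expect_rel(lateral_fwhm_profile(b, 2, step = 20), 2.3548 * sigma * 20,
             0.01)
  b2 <- b
  b2[, 2] <- pmax(b[, 2], exp(-(x - 20)^2 / (2 * sigma^2)))
  expect_error(lateral_fwhm_profile(b2, 2, step = 20),
               class = "ringpam_ambiguous_peak")
})

test_that("depth mapping masks pre-ring arrivals and preserves echoes", {
  v <- build_fiber_ascan_stack(noise_rms = 0,
                               scan = scan_pattern(100, c(5, 0.1)))
  env <- v
  env$samples <- envelope(v$samples)
  dv <- map_depth(env)
  expect_true(all(is.na(dv$samples[1, 1, dv$z < 0.01])) ||
                all(dim(dv$samples) > 0))
  # ridge of the depth-mapped volume follows the configured fiber line
  truth <- attr(v, "truth")
  iy <- which.max(apply(v$samples[1, , ], 1, max))
  ridge <- apply(dv$samples[, iy, ], 1, function(a) {
    a[is.na(a)] <- -Inf
    dv$z[which.max(a)]
  })
  expect_lt(max(abs(ridge - truth$z)), 0.05)
})

test_that("full chain recovers the 2 mm / 5 mm fiber tilt within 2%", {
  v <- build_fiber_ascan_stack(noise_rms = 0.02, seed = 11,
                               scan = scan_pattern(50, c(5, 0.1)))
  proc <- lowpass(v, cutoff = 30)
  proc$samples <- envelope(proc$samples)
  dv <- map_depth(proc)
  truth <- attr(v, "truth")
  iy <- which.max(apply(v$samples[1, , ], 1, max))
  ridge <- apply(dv$samples[, iy, ], 1, function(a) {
    a[is.na(a)] <- -Inf
    dv$z[which.max(a)]
  })
  on_fiber <- truth$x <= 5
  fit <- coef(lm(ridge[on_fiber] ~ truth$x[on_fiber]))
  span_recovered <- fit[2] * 5
  expect_rel(span_recovered, 2, 0.02)
})
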