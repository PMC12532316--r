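test_that("voxelized vessel volume matches the analytic cylinder", {
  ph <- build_vessel_phantom(vessel_spec(20, depth_of_top = 100),
                             dims = c(80, 40, 240), pitch = 1)
  n_vessel <- sum(ph$label == 3L)
  analytic <- pi * 10^2 * 40            # pi r^2 per unit length x ny
  expect_lt(abs(n_vessel - analytic) / analytic, 0.05)
})

test_that("cylinder discretization converges with pitch", {
  err_at <- function(pitch) {
    dims <- c(120, 8, 360) / pitch
    ph <- build_vessel_phantom(vessel_spec(60, depth_of_top = 50),
                               dims = dims, pitch = pitch,
                               water_depth = 20)
    n <- sum(ph$label == 3L) * pitch^3
    abs(n - pi * 30^2 * dims[2] * pitch) / (pi * 30^2 * dims[2] * pitch)
  }
  expect_lt(err_at(1), err_at(3))
})

test_that("degenerate vessels are rejected", {
  expect_error(vessel_spec(0), class = "ringpam_geometry_error")
  expect_error(vessel_spec(-5), class = "ringpam_geometry_error")
  # vessel deeper than the grid
  expect_error(
    build_vessel_phantom(vessel_spec(100, depth_of_top = 300),
                         dims = c(160, 20, 200)),
    class = "ringpam_geometry_error")
})

test_that("max vertical chord of a 100 um vessel is 100 voxels", {
  ph <- build_vessel_phantom(vessel_spec(100, depth_of_top = 50),
                             dims = c(160, 8, 300), pitch = 1)
  # chord through the axis: count vessel voxels along z at the centre column
  ic <- which.max(apply(ph$label[, 4, ] == 3L, 1, sum))
  chord <- sum(ph$label[ic, 4, ] == 3L)
  expect_lte(abs(chord - 100), 1)
})

test_that("every voxel label has a property entry", {
  ph <- build_vessel_phantom(vessel_spec(20), dims = c(60, 20, 220))
  expect_true(all(unique(as.vector(ph$label)) %in% ph$properties$label))
})

test_that("optical defaults describe a strongly absorbing vessel", {
  blood <- default_blood_properties()
  tissue <- default_tissue_properties()
  expect_gt(blood$mu_a, tissue$mu_a)
  expect_gt(blood$g, 0); expect_lt(blood$g, 1)
  expect_gt(tissue$g, 0); expect_lt(tissue$g, 1)
  # Beer-Lambert half-depth of blood absorption: tens of micrometres
  half_depth_um <- log(2) / blood$mu_a * 1e4
  expect_gt(half_depth_um, 10)
  expect_lt(half_depth_um, 100)
})

test_that("phantom TIFF round-trip preserves labels and metadata", {
  ph <- build_vessel_phantom(vessel_spec(20), dims = c(40, 10, 200))
  path <- file.path(tempdir(), "phantom_rt")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_identical(ph2$label, ph$label)
  expect_equal(ph2$pitch, ph$pitch)
  expect_equal(ph2$properties$mu_a, ph$properties$mu_a)
})

test_that("fiber A-scan stack is deterministic and follows the tilt", {
  v1 <- build_fiber_ascan_stack(noise_rms = 0.05, seed = 7,
                                scan = scan_pattern(50, c(5, 0.1)))
  v2 <- build_fiber_ascan_stack(noise_rms = 0.05, seed = 7,
                                scan = scan_pattern(50, c(5, 0.1)))
  expect_identical(v1$samples, v2$samples)

  # noiseless stack: arrival times follow t(x) = sqrt(z(x)^2 + r^2) / c
  v <- build_fiber_ascan_stack(noise_rms = 0,
                               scan = scan_pattern(100, c(5, 0.1)))
  truth <- attr(v, "truth")
  iy <- which.max(apply(v$samples[1, , ], 1, max))
  arrivals <- apply(v$samples[, iy, ], 1,
                    function(a) which.max(envelope(a)) * v$dt)
  expect_lt(max(abs(arrivals - truth$t)), 0.01)

  # depth slope recovered by least squares within 1 %
  z_rec <- time_to_depth(arrivals)
  slope <- coef(lm(z_rec ~ truth$x))[2]
  expect_rel(slope, 2 / 5, 0.01)
})

test_that("single scan position yields one echo at the configured depth", {
  v <- build_fiber_ascan_stack(fiber = fiber_spec(7, 2, 5),
                               scan = scan_pattern(5000, c(5, 0.01)),
                               noise_rms = 0)
  a <- envelope(v$samples[1, 1, ])
  t_peak <- which.max(a) * v$dt
  expect_rel(t_peak, depth_to_time(0.3), 0.01)
  expect_error(build_fiber_ascan_stack(noise_rms = -1),
               class = "ringpam_parameter_error")
})
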