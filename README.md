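# ringpam

Simulation workbench for **optical-resolution photoacoustic (optoacoustic)
microscopy with a spherically-focused thin ring-segment detector**.

Optical-resolution photoacoustic microscopy excites hemoglobin-rich
structures with a focused 532 nm nanosecond laser pulse and listens to the
resulting broadband ultrasound transient.  A low-NA GRIN lens (NA ≈ 0.06)
gives an *axially extended* optical focus, so a vessel lit along its depth
becomes an axially extended acoustic source — but a conventional focused
detector only hears well near its acoustic focus.  Opening the central
aperture of a spherical detector until only a thin (100 µm) ring remains
yields a thread-like axial sensitivity zone (an extended acoustic depth of
field) and, for axially extended sources, a *larger* signal than the full
aperture it was cut from.  `ringpam` reproduces that numerical study as a
tested, reusable pipeline for people designing or analysing such systems:

* **Monte-Carlo photon transport** in voxelized two-layer vessel phantoms
  (`build_vessel_phantom()`, `trace_photons()`): weighted photons,
  Henyey–Greenstein scattering, Russian roulette, focused-Gaussian launch;
  absorbed-energy grids, axial profiles and their FWHM.
* **2D k-space pseudospectral acoustics** (`propagate()`): first-order
  coupled pressure/velocity scheme with the `sinc(ckΔt/2)` temporal
  correction (exact for homogeneous media), quadratic power-law water
  absorption `α(f) = 0.0022 f²` dB/cm as an exact spectral filter, and a
  split-field absorbing boundary layer; 5 µm / 1 ns grid, 150 MHz band.
* **Ring-segment detector model** (`ring_geometry()`,
  `simulate_detection()`, `sensitivity_sweep()`, `na_sweep()`,
  `reception_field()`): geometry from aperture + working distance
  (`R = √((D/2)² + WD²)` → R = 2.75 mm, NA = 0.84 for the reference
  device), arc-element sampling, pressure-averaging aggregation,
  aperture/NA/bandwidth sweeps reusing one stored propagation, and axial
  reception fields (depth of field) via reciprocity.
* **A-scan processing** (`lowpass()`, `envelope()`, `map_depth()`,
  `mip()`, `spectrum_stats()`): 30 MHz zero-phase low-pass, Hilbert
  envelope, the ring detector's nonlinear time-to-depth transform
  `z = √(c²t² − r²)`, maximum-intensity projections, plus the closed-form
  estimators `RA = 0.88·c/Δf` and `w₀ ≈ 0.5·λ/NA`.
* **Synthetic data** for every stage, including the tilted 7 µm fiber
  phantom (`build_fiber_ascan_stack()`), and experiment recipes with
  config hashes and run manifests (`run_recipe()`, `validate_config()`).

Results come back as tibbles (sweeps, profiles, fields) with
`tidy()`/`glance()` methods and `autoplot()` graphics, so they drop
straight into dplyr/ggplot2 workflows.

## A worked example

```r
library(ringpam)

## detector geometry of the reference device
geom <- ring_geometry(outer_aperture = 4.6, working_distance = 1.5)
geom
#> <ring_geometry> R = 2.746 mm, D = 4.60 mm, d = 0.00 mm, WD = 1.500 mm, NA = 0.838
#>   arc: 0.0..56.9 degrees from the axis (both signs)
ring_geometry(ring_width = 0.1)     # thin 100-um ring segment
#> <ring_geometry> R = 2.746 mm, D = 4.60 mm, d = 4.49 mm, WD = 1.500 mm, NA = 0.838
#>   arc: 54.8..56.9 degrees from the axis (both signs)

## closed-form optics/resolution estimates
focal_waist(532, 0.06)        # 4.43 um optical waist
axial_resolution(28, 1.5)     # 47.1 um axial resolution at 28 MHz bandwidth

## absorbed energy in a 20-um vessel at 100 um depth
ph   <- build_vessel_phantom(vessel_spec(20, depth_of_top = 100),
                             dims = c(120, 120, 300))
grid <- trace_photons(ph, beam_spec(), photon_budget(2e5, seed = 1))
glance(grid)
#> # A tibble: 1 x 5
#>   launched absorbed escaped      residual absorbed_fraction
#> 1   200000   77817. 122183. 0.00000000469             0.389
fwhm(extract_axial_profile(grid))
#> [1] 19.7
```

The derived focal radius (2.75 mm) and acoustic NA (0.84) match the
closed-form design values; the photon bookkeeping shows weight
conservation to floating-point; and the 19.7 µm absorbed-energy FWHM is
the depth extent of the optoacoustic source formed in a 20 µm capillary —
essentially the vessel diameter, because blood absorbs 532 nm light over a
half-depth of ~29 µm.

The heavier figure-level experiments are packaged as recipes:

```r
cfg <- experiment_config(master_seed = 1, out_dir = "out")
run_recipe("fig4_aperture_sweep", cfg)   # sensitivity vs central aperture
run_recipe("fig4_reception_field", cfg)  # axial reception field / DOF
```

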