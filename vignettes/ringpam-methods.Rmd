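---
title: "Modelling a thin ring-segment detector for extended-depth-of-field photoacoustic microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a thin ring-segment detector for extended-depth-of-field photoacoustic microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ringpam)
```

## The problem

Optical-resolution photoacoustic (optoacoustic) microscopy probes tissue
with a focused nanosecond laser beam at 532 nm; absorbing structures —
above all haemoglobin in blood vessels — convert the pulse into a broadband
ultrasound transient that a focused detector picks up.  The lateral
resolution comes from the optical focus, depth from the acoustic
time-of-flight.  A low-NA gradient-index (GRIN) lens gives an axially
*extended* optical focus (millimetre-scale), but a conventional spherically
focused detector hears well only within a few hundred micrometres of its
acoustic focus.  The system modelled here closes that gap with a
spherically-focused detector whose central aperture is opened so wide that
only a thin (100 µm) ring remains active: the ring sees a *thread-like*
axial sensitivity zone (an extended acoustic depth of field) and — for
axially extended sources such as capillaries lit along their depth — even a
*higher* signal than the full aperture it was cut from.

`ringpam` re-implements the full numerical study behind that design as a
reusable pipeline with four stages:

1. **Photon transport** (`trace_photons()`): weighted-photon Monte-Carlo in
   a voxelized two-layer (water/tissue) phantom with cylindrical vessels,
   on a 1 µm grid.
2. **Acoustic propagation** (`propagate()`): 2D k-space pseudospectral
   time-domain solver, 5 µm / 1 ns grid, water with quadratic power-law
   absorption (0.0022 dB MHz⁻² cm⁻¹), supporting frequencies to 150 MHz.
3. **Detector model** (`ring_geometry()`, `simulate_detection()`,
   `reception_field()`): parametric spherically-focused ring segment,
   element-trace aggregation, aperture/NA/bandwidth sweeps, axial reception
   fields.
4. **Reconstruction** (`lowpass()`, `envelope()`, `map_depth()`, `mip()`):
   the A-scan processing chain with the ring detector's nonlinear
   time-to-depth transform `z = sqrt(c²t² − r²)`.

## Photon transport and the absorbed-energy profiles

The Monte-Carlo follows the standard weighted-photon scheme: free paths are
exponential in `mu_t = mu_a + mu_s`, consumed voxel-by-voxel; at every
interaction the photon deposits `w · mu_a/mu_t` in the current voxel and
scatters into a Henyey–Greenstein deflection with anisotropy `g`; Russian
roulette (threshold 1e-4, survival 0.1) terminates low-weight photons
unbiasedly.  With roulette disabled the weight bookkeeping
(absorbed + escaped = launched) is exact to floating-point, which the test
suite asserts.

The beam launch model samples, independently per photon, a waist crossing
point (Gaussian, 1/e² intensity radius `w0 = λ/(π NA)` ≈ 2.8 µm) and a
propagation slope (Gaussian, 1/e² half-angle `asin(NA/n)`), and aims the
photon through the waist point.  Independent position/slope sampling
reproduces the Gaussian-beam caustic `w(z)² = w0² + θ²z²` with a Rayleigh
range of about 63 µm — the axially extended focus that motivates the whole
design.  Each photon derives its own counter-seeded random stream from the
master seed, so runs are bit-reproducible and independent of execution
order.

### Optical property defaults and how they were chosen

The coefficients of the two-layer medium are single-sourced constants
(`default_blood_properties()` etc.), not scattered literals, and every one
can be overridden.  Published values at 532 nm span wide ranges, so the
defaults were *identified*: they must lie inside the published ranges and
reproduce the absorbed-energy depth profiles that the study design builds
on (on-axis FWHM of ≈19/32/51 µm in 20/50/100 µm vessels at 100 µm depth).
Two constraints fall out of the physics:

* **Vessel interior = haemoglobin solution.**  `mu_a = 236 cm⁻¹`
  (oxygenated haemoglobin at 150 g/L), `mu_s = 0`.  Whole-blood RBC
  scattering (`mu_s` of several hundred cm⁻¹) would make the *on-axis*
  profile decay at `mu_a + mu_s`, capping the FWHM near 20 µm for every
  vessel size — incompatible with a 51 µm width in the 100 µm vessel.  The
  absorption-dominated haemoglobin model is also what "optical properties
  of haemoglobin" means in the tissue-optics literature.
* **Quasi-ballistic superficial layer.**  `mu_a = 3 cm⁻¹`,
  `mu_s = 20 cm⁻¹`, `g = 0.9` (reduced scattering 2 cm⁻¹, the low end of
  soft-tissue compilations).  Dermis-level scattering (`mu_s` ≈ 250 cm⁻¹)
  over the first 100 µm would wash out the focal caustic whose on-axis
  intensity boost is what stretches the 100 µm-vessel profile to ~50 µm;
  the reference widths therefore pin the layer to weak scattering.

The axial profile is extracted on-axis with 3 × 3-voxel lateral averaging
by default (`extract_axial_profile()`); a laterally integrated mode is
provided because either could be meant by a published "profile".  Averaging
over a window comparable to the beam waist dilutes the caustic and biases
the largest-vessel width low by roughly 10 %; a single-voxel profile
(`lateral_halfwidth = 0`) trades that bias for more Monte-Carlo noise.

## The acoustic solver

`propagate()` advances the coupled first-order pressure/velocity system on
spatially staggered grids with exact spectral derivatives and the k-space
temporal correction `sinc(c k Δt/2)` — for a homogeneous medium the scheme
is then exact, which the suite verifies by advecting a travelling wave
around a periodic domain and recovering the initial field to 1e-9.
Stability is enforced at CFL ≤ 0.3 (`c Δt/Δx = 0.3` at the 5 µm / 1 ns
defaults; maximum supported frequency `c/2Δx` = 150 MHz).

Absorption follows `α(f) = α₀ f²` with `α₀ = 0.0022 dB MHz⁻² cm⁻¹`
(water).  For the quadratic exponent the standard lossy-medium model has no
dispersion correction, so the law is applied as an exact per-step spectral
amplitude filter on the stored velocity fields; a 50 MHz packet over 1 mm
loses 0.55 dB, matched by the tests to the closed form.

Boundaries use a 20-cell split-field absorbing layer with quartic grading
(peak damping 2 Np per grid point); the measured broadband reflection of a
normally incident pulse is below −45 dB, asserted in the suite.  Initial
pressure is released as-is by default.  A radially symmetric Blackman
k-space window (`smooth_source = TRUE`) is available to emulate solvers
that smooth their source terms (it also keeps a band-limited single-cell
source isotropic on the Cartesian grid), but it visibly suppresses the
>75 MHz content on which the thin-ring sensitivity advantage rides, so it
is off by default.

## Detector model

`ring_geometry()` derives the focal radius from the aperture and working
distance, `R = sqrt((D/2)² + WD²)` — 2.75 mm for D = 4.6 mm and
WD = 1.5 mm, with acoustic NA `(D/2)/R = 0.84`.  In the 2D simulation
plane the detector is the arc of radius R about the focus between the
central-hole cone and the outer-aperture cone; a central aperture `d > 0`
leaves two symmetric arc segments.  Out-of-plane (annular) weighting is
deliberately not applied: the acoustic stage is a 2D model throughout,
and 3D ring weighting is noted as an extension.

The detector output is the **arc-length-weighted mean** of the element
pressures: a piezo element integrates stress over its active area, and all
elements are equidistant `R` from the focus, so focal arrivals are
coherent without added delays.  A sum convention would scale with active
area and could never show a thin ring outperforming the full cap.

**Amplitude metric.**  Each aggregated signal carries both its Hilbert-
envelope maximum (`amplitude_env`) and its raw peak-to-peak
(`amplitude_pp`); sweeps report the envelope maximum as the canonical
amplitude.  The choice is empirical as well as conventional: optoacoustic
amplitudes are conventionally read as envelope maxima (the imaging chain
itself detects envelope peaks), and the peak-to-peak of the *mean* trace
systematically understates the gain of edge-dominated apertures because
the differently shaped element pulses partially fill each other's troughs.

One propagation per source is stored as a dense element-trace set
(`simulate_detection()`), and every aperture, angular coverage and
bandwidth variant is evaluated by re-aggregating those traces
(`sensitivity_sweep()`, `na_sweep()`, `aggregate_detector()`), which turns
the sweep figures into seconds of post-processing.  Band limiting is a
zero-phase 4th-order Butterworth low-pass (`apply_band_limit()`), shared
with the reconstruction stage.

### Reception field and depth of field

`reception_field()` computes the detector response versus the axial
position of a small source.  The default route uses acoustic reciprocity —
the transmit field of the active arc equals its receive sensitivity — so
one run yields the whole axial field; a per-z reference route propagates a
source from every axial position and aggregates the element traces, and
the two agree within 3 % in the suite.  The acoustic depth of field is the
FWHM of this field (`dof_fwhm`; the level is configurable since a −6 dB
reading of the published field would be the same quantity at 0.5).

The axial extent of a thin ring's reception field is set by coherence
across the ring: a source displaced by `δz` from the focus spreads its
arrivals over `δz·(cos θ_i − cos θ_o)/c` across the active arc, so the
field's width is inversely proportional to `cos θ_i − cos θ_o` and
directly proportional to the duration (inverse bandwidth) of the received
pulse.  Both the ring-width convention and the probe's spectral content
therefore move the number; see the design-choices section.

## Reconstruction

The processing chain mirrors standard ring-detector practice: 30 MHz
zero-phase low-pass, Hilbert envelope (analytic-signal magnitude),
nonlinear time-to-depth resampling `z = sqrt(c²t² − r²)` with `r = 2.3 mm`
(samples with `ct < r` are masked, never fabricated), and maximum
intensity projections.  Closed-form estimators accompany the chain: axial
resolution `RA = 0.88 c/Δf` (47.1 µm at Δf = 28 MHz and c = 1.5 mm/µs —
a published rounding to 48 µm implies c ≈ 1.53; both inputs are exposed)
and optical waist `w0 ≈ 0.5 λ/NA` (4.4 µm at 532 nm, NA 0.06).

## Synthetic data

The generator builds every input the pipeline needs: voxel phantoms with a
horizontal cylindrical vessel (1 µm pitch, z down, voxel centres at
`(i−0.5)·pitch`), and A-scan stacks of a tilted 7 µm fiber (2 mm depth
drop over 5 mm, 20 µm scan steps) whose echoes follow the ring
time-of-flight rule with a gated derivative-of-Gaussian wavelet (~30 MHz
band) and additive Gaussian noise.  It emulates the geometry and the
first-order statistics of such acquisitions — not laser energy drift,
surface topography, motion, or frequency-dependent detector response — so
passing the chain tests shows the *transforms* are right, not that real
tissue data will look this clean.

## Design choices on genuinely open points

* **Ring-width convention.**  "Ring width 100 µm" can be measured on the
  aperture plane (`d = D − 2w`, inner aperture 4.40 mm, arc 3.6°) or along
  the detector surface (`θ_i = θ_o − w/R`, inner aperture 4.49 mm, arc
  2.1°).  The package exposes both (`ring_width_convention`); the surface
  reading matches a fabricated film strip of constant width and is the
  default for the thin-segment mode.  The reception-field width scales as
  `1/(cos θ_i − cos θ_o)` and so differs by ~1.7× between conventions —
  by far the largest single modelling lever in the detector stage.
* **Reception-field probe.**  An ideal one-cell source carries content to
  the grid's 150 MHz and yields the narrowest possible axial field; any
  physical "point" source (a capillary-scale absorber, or a solver that
  smooths its source term) is band-limited to a few tens of MHz through
  its transit time and widens the field markedly — between an ideal point
  and a 30 µm probe the thin ring's measured depth of field roughly
  triples.  The default is the ideal point (the literal reading of a
  point-source probe); `probe_diameter` models a finite probe explicitly,
  implemented in the reciprocity route as the disc's chord-projection
  kernel on the axis signals and in the per-z route as a source patch of
  that size.  Published thread-field lengths measured with an unspecified
  small source are therefore expected to exceed the ideal-point value.
* **Mode of the absorbed-energy profile** (on-axis vs laterally
  integrated): both implemented, on-axis default, see above.
* **Amplitude metric**: envelope maximum, peak-to-peak retained, see
  above.

## Problem sizes and determinism

The full-scale runs used throughout the tests and the acceptance script
are: acoustic grids of roughly 1000 × 650 cells at 5 µm with ~1900–2600
time steps of 1 ns (one run per source length or reception field);
Monte-Carlo studies of 1–2 × 10⁶ photons per vessel on cropped
160 × 160 × 300–400 voxel grids at 1 µm.  Scaled-down geometries (0.7 mm
focal radius) carry the monotonicity and cross-route properties.  All
stochastic stages derive per-photon counter seeds from one master seed and
are bit-reproducible; the acoustic stages are deterministic.

## Known limitations

* The acoustic stage is 2D; out-of-plane focusing gain and the annular
  element weighting of a real 3D ring are not modelled.
* Heterogeneous sound speed/density, nonlinearity, shear waves and
  transducer electromechanics (impulse response, amplifier noise) are out
  of scope; bandwidth limits are modelled as post-hoc filters.
* The Monte-Carlo ignores refractive-index mismatch between water and
  tissue (both aqueous) and polarization.
* Published amplitude gains are reproduced to within ~5–10 % but not
  exactly; the residual depends on unstated details of the original
  aggregation ("detection efficiency") and source smoothing, as discussed
  above.
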