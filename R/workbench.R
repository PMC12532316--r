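#' Experiment configuration
#'
#' One structured configuration object drives all pipeline stages; every
#' recipe records its hash in the run manifest so outputs are traceable.
#' `scale` shrinks the stochastic and sampling workload (photon budget,
#' element density, axial sampling) for smoke runs without touching the
#' physics (grid steps, geometry).
#'
#' @param master_seed Integer seed from which all stage seeds derive.
#' @param scale Workload scale factor in (0, 1].
#' @param out_dir Output directory for recipe results.
#' @param ... Named overrides of the stage defaults (see the returned
#'   object).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(master_seed = 1L, scale = 1, out_dir = tempdir(),
                              ...) {
  if (scale <= 0 || scale > 1)
    .stop2("`scale` must be in (0, 1]", "ringpam_parameter_error")
  cfg <- list(
    master_seed = as.integer(master_seed),
    scale = scale,
    out_dir = out_dir,
    dx = 0.005, dt = 0.001, pml = 20L,
    sound_speed = 1.5, alpha0 = 0.0022,
    outer_aperture = 4.6, working_distance = 1.5, ring_width = 0.1,
    beam_na = 0.06, wavelength = 532,
    n_photons = 1e6,
    vessel_diameters = c(20, 50, 100), vessel_depth = 100,
    source_lengths = c(20, 30, 50), band_limit = 30,
    reception_z = c(-1.4, 1.4), reception_n_z = 57
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    .stop2(paste("unknown config fields:", paste(unknown, collapse = ", ")),
           "ringpam_parameter_error")
  cfg[names(over)] <- over
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> seed %d, scale %g, hash %s\n",
              x$master_seed, x$scale, config_hash(x)))
  invisible(x)
}

#' Hash of a configuration (for run manifests)
#'
#' @param config An [experiment_config()].
#' @return MD5 hex digest of the canonical JSON serialisation.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Validate a configuration
#'
#' Checks the acoustic stability (CFL) condition, boundary-layer margins,
#' detector geometry invariants and seed presence; returns the violations
#' instead of erroring.
#'
#' @param config An [experiment_config()].
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  cfl <- config$sound_speed * config$dt / config$dx
  if (cfl > 0.3)
    v <- c(v, sprintf("CFL violation: c*dt/dx = %.3f > 0.3", cfl))
  if (config$pml < 10)
    v <- c(v, "absorbing boundary layer thinner than 10 cells")
  d <- config$outer_aperture - 2 * config$ring_width
  if (d >= config$outer_aperture || config$ring_width <= 0)
    v <- c(v, "geometry violation: central aperture d must satisfy 0 <= d < D")
  if (is.null(config$master_seed) || is.na(config$master_seed))
    v <- c(v, "missing master seed")
  if (config$beam_na <= 0 || config$beam_na >= 1)
    v <- c(v, "beam NA must be in (0, 1)")
  if (!is.null(config$band_limit) &&
      config$band_limit >= 1 / (2 * config$dt))
    v <- c(v, "band limit at or above Nyquist")
  v
}

.write_table <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run a named experiment recipe
#'
#' Executes the stage chain for one of the canned simulation experiments and
#' writes its result tables (CSV) to `config$out_dir`:
#'
#' * `fig2_fwhm`: absorbed-energy FWHM versus vessel diameter (Monte-Carlo).
#' * `fig3_directivity`: angular pattern of a 20-um line source.
#' * `fig3_na_sweep`: aggregate amplitude versus acoustic NA.
#' * `fig4_aperture_sweep`: amplitude versus central aperture, full band.
#' * `fig5_bandwidth`: same sweep under the band limit.
#' * `fig4_reception_field`: axial reception field and DOF of the thin ring.
#' * `recon_fiber_demo`: synthetic tilted-fiber stack through the full
#'   processing chain (low-pass, envelope, depth mapping, MIP).
#'
#' @param name Recipe name (see above).
#' @param config An [experiment_config()].
#' @return A list with `manifest` (config hash, versions, timings, outputs)
#'   and `results` (the tables/objects, in memory).
#' @export
run_recipe <- function(name = c("fig2_fwhm", "fig3_directivity",
                                "fig3_na_sweep", "fig4_aperture_sweep",
                                "fig5_bandwidth", "fig4_reception_field",
                                "recon_fiber_demo"),
                       config = experiment_config()) {
  name <- match.arg(name)
  stopifnot(inherits(config, "experiment_config"))
  viol <- validate_config(config)
  if (length(viol) > 0)
    .stop2(paste("invalid config:", paste(viol, collapse = "; ")),
           "ringpam_config_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  sc <- config$scale
  geom_full <- ring_geometry(config$outer_aperture, config$working_distance)
  geom_ring <- ring_geometry(config$outer_aperture, config$working_distance,
                             ring_width = config$ring_width)
  med <- acoustic_medium(config$sound_speed, config$alpha0)
  spacing <- config$dx / sc
  outputs <- character(0)
  results <- list()

  if (name == "fig2_fwhm") {
    tab <- vessel_fwhm_study(
      config$vessel_diameters, depth = config$vessel_depth,
      beam = beam_spec(config$wavelength, config$beam_na),
      budget = photon_budget(max(1e4, config$n_photons * sc),
                             seed = config$master_seed))
    results$fwhm <- tab
    outputs <- .write_table(tab, config$out_dir, "fig2_fwhm")
  } else if (name == "fig3_directivity") {
    tab <- directivity_of_line_source(
      config$source_lengths[1], radius = geom_full$focal_radius,
      n_angles = max(9, round(19 * sc)), medium = med,
      dx = config$dx, dt = config$dt, pml = config$pml)
    results$directivity <- tab
    outputs <- .write_table(tab, config$out_dir, "fig3_directivity")
  } else if (name == "fig3_na_sweep") {
    tab <- na_sweep(config$source_lengths[1],
                    na_values = seq(0.3, 1, by = 0.1),
                    focal_radius = geom_full$focal_radius, medium = med,
                    spacing = spacing, dx = config$dx, dt = config$dt,
                    pml = config$pml)
    results$na_sweep <- tab
    outputs <- .write_table(tab, config$out_dir, "fig3_na_sweep")
  } else if (name %in% c("fig4_aperture_sweep", "fig5_bandwidth")) {
    bl <- if (name == "fig5_bandwidth") config$band_limit else NULL
    apertures <- c(0, 2, 3, 4, geom_ring$central_aperture)
    tabs <- lapply(config$source_lengths, function(L) {
      run <- simulate_detection(L, geom = geom_full, medium = med,
                                spacing = spacing, dx = config$dx,
                                dt = config$dt, pml = config$pml)
      tab <- sensitivity_sweep(run, apertures, band_limit = bl)
      tab$source_length <- L
      tab$ratio_to_full <- tab$amplitude / tab$amplitude[1]
      tab
    })
    tab <- dplyr::bind_rows(tabs)
    results$sweep <- tab
    outputs <- .write_table(tab, config$out_dir, name)
  } else if (name == "fig4_reception_field") {
    rf <- reception_field(geom_ring, z_range = config$reception_z,
                          n_z = max(11, round(config$reception_n_z * sc)),
                          medium = med, dx = config$dx, dt = config$dt,
                          pml = config$pml)
    results$reception_field <- rf
    outputs <- .write_table(tidy(rf), config$out_dir, name)
  } else if (name == "recon_fiber_demo") {
    vol <- build_fiber_ascan_stack(noise_rms = 0.02,
                                   seed = config$master_seed)
    proc <- lowpass(vol, cutoff = config$band_limit)
    proc$samples <- envelope(proc$samples)
    dv <- map_depth(proc)
    img <- mip(dv, axis = 2)
    ridge <- apply(dv$samples[, which.max(apply(vol$samples, 2, max)), ],
                   1, function(v) if (all(is.na(v))) NA_real_
                                  else which.max(v))
    tab <- tibble::tibble(x = (seq_len(nrow(img)) - 1) * vol$scan_step / 1000,
                          ridge_z = dv$z[ridge])
    results$volume <- dv
    results$ridge <- tab
    p1 <- .write_table(tab, config$out_dir, "recon_fiber_ridge")
    img_path <- file.path(config$out_dir, "recon_fiber_mip.tif")
    m <- img; m[!is.finite(m)] <- 0
    tiff::writeTIFF(m / max(m), img_path, bits.per.sample = 16L)
    outputs <- c(p1, img_path)
  }

  manifest <- list(
    recipe = name,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("ringpam")),
    r_version = as.character(getRversion()),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    wall_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = outputs
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, results = results)
}
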