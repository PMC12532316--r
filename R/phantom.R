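#' Cylindrical vessel specification
#'
#' A blood-filled cylinder embedded in the tissue layer.  The vessel axis is
#' horizontal and, by default, perpendicular to the simulated B-scan (x-z)
#' plane, i.e. it runs along y through the whole grid.
#'
#' @param diameter Vessel diameter in um (> 0).
#' @param depth_of_top Depth of the uppermost vessel surface below the
#'   water/tissue interface, in um (>= 0).
#' @param properties [optical_properties()] of the vessel content.
#' @return An object of class `vessel_spec`.
#' @examples
#' vessel_spec(20, depth_of_top = 100)
#' @export
vessel_spec <- function(diameter, depth_of_top = 100,
                        properties = default_blood_properties()) {
  if (!is.numeric(diameter) || length(diameter) != 1 || is.na(diameter) ||
      diameter <= 0)
    .stop2("`diameter` must be a single positive length (um)",
           "ringpam_geometry_error")
  if (!is.numeric(depth_of_top) || depth_of_top < 0)
    .stop2("`depth_of_top` must be >= 0", "ringpam_geometry_error")
  stopifnot(inherits(properties, "optical_properties"))
  structure(list(diameter = diameter, depth_of_top = depth_of_top,
                 properties = properties),
            class = "vessel_spec")
}

#' Build a voxelized two-layer vessel phantom
#'
#' Discretizes a two-layer medium (water above tissue) with a horizontal
#' cylindrical vessel onto a regular voxel grid.  Voxel centres sit at
#' `(i - 0.5) * pitch` along each axis (1-based indices); z increases
#' downward from the top (water) face of the grid.
#'
#' @param vessel A [vessel_spec()].
#' @param tissue,water [optical_properties()] of the two layers.
#' @param water_depth Thickness of the water layer in um.
#' @param dims Integer grid size `c(nx, ny, nz)` in voxels.
#' @param pitch Voxel pitch in um (default 1).
#' @return A `voxel_phantom`: list with the integer `label` array
#'   (1 = water, 2 = tissue, 3 = vessel), the `properties` table, `pitch`,
#'   `water_depth` and the vessel geometry.
#' @examples
#' ph <- build_vessel_phantom(vessel_spec(20), dims = c(60, 40, 220))
#' table(ph$label)
#' @export
build_vessel_phantom <- function(vessel,
                                 tissue = default_tissue_properties(),
                                 water = default_water_properties(),
                                 water_depth = 50,
                                 dims = c(160L, 160L, 360L),
                                 pitch = 1) {
  stopifnot(inherits(vessel, "vessel_spec"), length(dims) == 3, pitch > 0)
  dims <- as.integer(dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  zc_top <- water_depth + vessel$depth_of_top          # um, top of vessel
  r <- vessel$diameter / 2
  zc <- zc_top + r                                     # axis depth
  xc <- nx * pitch / 2
  if (zc + r > nz * pitch || zc - r < water_depth ||
      xc - r < 0 || xc + r > nx * pitch)
    .stop2("vessel does not fit inside the tissue region of the grid",
           "ringpam_geometry_error")

  lab <- array(2L, dim = c(nx, ny, nz))
  z_centres <- (seq_len(nz) - 0.5) * pitch
  n_water <- sum(z_centres <= water_depth)
  if (n_water > 0) lab[, , seq_len(n_water)] <- 1L

  # vessel: cylinder along y, centred in x
  x_centres <- (seq_len(nx) - 0.5) * pitch
  d2 <- outer((x_centres - xc)^2, (z_centres - zc)^2, `+`)
  inside <- d2 <= r^2                                  # nx x nz mask
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    for (jy in seq_len(ny)) {
      lab[cbind(idx[, 1], jy, idx[, 2])] <- 3L
    }
  }

  props <- tibble::tibble(
    material = c("water", "tissue", "vessel"),
    label = 1:3,
    mu_a = c(water$mu_a, tissue$mu_a, vessel$properties$mu_a),
    mu_s = c(water$mu_s, tissue$mu_s, vessel$properties$mu_s),
    g = c(water$g, tissue$g, vessel$properties$g)
  )
  structure(list(label = lab, properties = props, pitch = pitch,
                 water_depth = water_depth, vessel = vessel,
                 dims = dims),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels at %g um pitch\n",
              x$dims[1], x$dims[2], x$dims[3], x$pitch))
  cat(sprintf("  water layer: %g um; vessel: %g um diameter, top at %g um\n",
              x$water_depth, x$vessel$diameter, x$vessel$depth_of_top))
  invisible(x)
}

#' Write / read a voxel phantom as a TIFF stack with a JSON sidecar
#'
#' The label grid is stored as a multi-page 8-bit TIFF (one page per z slice)
#' and the voxel pitch plus the material property table in
#' `<path>_meta.json`.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output path prefix (without extension).
#' @return `write_phantom()` returns `path` invisibly; `read_phantom()`
#'   returns the reconstructed `voxel_phantom`.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  pages <- lapply(seq_len(phantom$dims[3]), function(k)
    phantom$label[, , k] / 255)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 8L)
  meta <- list(pitch = phantom$pitch, water_depth = phantom$water_depth,
               dims = phantom$dims,
               vessel = list(diameter = phantom$vessel$diameter,
                             depth_of_top = phantom$vessel$depth_of_top),
               properties = phantom$properties)
  jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  dims <- as.integer(meta$dims)
  lab <- array(0L, dim = dims)
  for (k in seq_len(dims[3]))
    lab[, , k] <- as.integer(round(pages[[k]] * 255))
  props <- tibble::as_tibble(meta$properties)
  vs <- vessel_spec(meta$vessel$diameter, meta$vessel$depth_of_top,
                    optical_properties(props$mu_a[3], props$mu_s[3],
                                       props$g[3]))
  structure(list(label = lab, properties = props, pitch = meta$pitch,
                 water_depth = meta$water_depth, vessel = vs, dims = dims),
            class = "voxel_phantom")
}
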