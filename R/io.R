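# Persistence of trace sets: a simple directory container (TSV matrices with
# a JSON metadata sidecar carrying dt, sensor geometry and the config hash).

#' Write / read a pressure trace set
#'
#' Stores the trace matrix as TSV together with a JSON sidecar holding the
#' time step, sensor positions and (optionally) a configuration hash, so a
#' stored run can be re-aggregated later.
#'
#' @param traces A `pressure_traces`.
#' @param dir Output directory (created if needed).
#' @param config_hash Optional hash string recorded in the sidecar.
#' @return `write_traces()` returns `dir` invisibly; `read_traces()` returns
#'   the `pressure_traces`.
#' @export
write_traces <- function(traces, dir, config_hash = NULL) {
  stopifnot(inherits(traces, "pressure_traces"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(traces$traces, file.path(dir, "traces.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  meta <- list(dt = traces$dt, n_t = nrow(traces$traces),
               n_sensors = ncol(traces$traces),
               sensors = list(x = traces$sensors$x, z = traces$sensors$z),
               interpolation = attr(traces$sensors, "interpolation"),
               config_hash = config_hash)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(dir, "traces.tsv"),
                                   sep = "\t"))
  dimnames(m) <- NULL
  structure(list(traces = m, dt = meta$dt,
                 t = seq_len(meta$n_t) * meta$dt,
                 sensors = sensor_points(meta$sensors$x, meta$sensors$z,
                                         meta$interpolation),
                 p_final = NULL, energy = NULL, grid = NULL,
                 medium = NULL),
            class = "pressure_traces")
}
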