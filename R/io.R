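#' Write / read a trace as CSV plus JSON sidecar
#'
#' The CSV holds columns `time_ms`, `value`; the sidecar (same path with
#' `.json` appended) records the unit, sampling interval, protocol,
#' junction flag and any generator metadata (seed, ground-truth event
#' times).
#'
#' @param trace an [ephys_trace()].
#' @param path CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the reconstructed [ephys_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  utils::write.csv(data.frame(time_ms = trace_time(trace),
                              value = trace$samples),
                   path, row.names = FALSE)
  side <- list(unit = trace$unit, dt_ms = trace$dt,
               junction_corrected = trace$junction_corrected,
               protocol = if (is.null(trace$protocol)) NULL
                          else unclass(trace$protocol),
               meta = trace$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- NULL
  if (!is.null(side$protocol))
    proto <- do.call(step_protocol, side$protocol[c(
      "holding_target", "step_amp", "onset", "duration", "n_steps",
      "step_increment")])
  ephys_trace(df$value, dt = side$dt_ms, unit = side$unit, protocol = proto,
              junction_corrected = isTRUE(side$junction_corrected),
              meta = if (is.null(side$meta)) list() else side$meta)
}

#' Write / read a vesicle map as CSV plus JSON sidecar
#'
#' The CSV holds one vesicle per row (`vesicle_id`, `x_nm`, `y_nm`,
#' `diameter_nm`, `is_dcv`); the sidecar records the active-zone
#' endpoints, presynaptic area, PSD flag and generator metadata.
#'
#' @param map a [vesicle_map()].
#' @param path CSV path.
#' @return `write_vesicle_map` returns `path` invisibly;
#'   `read_vesicle_map` returns the reconstructed [vesicle_map()].
#' @export
write_vesicle_map <- function(map, path) {
  stopifnot(inherits(map, "vesicle_map"))
  utils::write.csv(map$vesicles, path, row.names = FALSE)
  side <- list(synapse_id = map$synapse_id,
               active_zone_nm = map$active_zone,
               presynaptic_area_um2 = map$presyn_area,
               psd_defined = map$psd_defined, meta = map$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_vesicle_map
#' @export
read_vesicle_map <- function(path) {
  ves <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vesicle_map(ves, active_zone = unlist(side$active_zone_nm),
              presyn_area = side$presynaptic_area_um2,
              psd_defined = isTRUE(side$psd_defined),
              synapse_id = side$synapse_id,
              meta = if (is.null(side$meta)) list() else side$meta)
}

#' Write / read a morphology as SWC plus spine CSV
#'
#' Standard 7-column SWC; the spine table, when present, is written next
#' to it as `<path>.spines.csv`.
#'
#' @param m a [neuron_morphology()].
#' @param path SWC path.
#' @return `write_morphology` returns `path` invisibly;
#'   `read_morphology` returns the reconstructed [neuron_morphology()].
#' @export
write_morphology <- function(m, path) {
  stopifnot(inherits(m, "neuron_morphology"))
  con <- file(path, "w")
  writeLines("# SWC: id type x y z radius parent", con)
  utils::write.table(m$nodes, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  if (!is.null(m$spines))
    utils::write.csv(m$spines, paste0(path, ".spines.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  nodes <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
  spath <- paste0(path, ".spines.csv")
  spines <- if (file.exists(spath)) utils::read.csv(spath) else NULL
  neuron_morphology(nodes, spines)
}
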