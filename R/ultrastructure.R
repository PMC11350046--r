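#' Apply the synapse inclusion filter
#'
#' A synapse enters the ultrastructural analysis only when its
#' postsynaptic density is defined and its synaptic-vesicle count
#' (dense-core vesicles excluded) lies between `min_sv` and `max_sv`
#' inclusive.
#'
#' @param maps list of [vesicle_map()] objects.
#' @param min_sv,max_sv inclusive vesicle-count bounds (defaults 10 and
#'   250).
#' @return The included subset of `maps`.
#' @export
filter_synapses <- function(maps, min_sv = 10, max_sv = 250) {
  keep <- vapply(maps, function(m) {
    stopifnot(inherits(m, "vesicle_map"))
    n <- sum(!m$vesicles$is_dcv)
    m$psd_defined && n >= min_sv && n <= max_sv
  }, logical(1L))
  maps[keep]
}

# distance from points (x, y) to the segment (x1,y1)-(x2,y2)
point_segment_distance <- function(x, y, seg) {
  p1 <- seg[1:2]; p2 <- seg[3:4]
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- pmin(pmax(((x - p1[1L]) * d[1L] + (y - p1[2L]) * d[2L]) / len2, 0), 1)
  sqrt((x - (p1[1L] + t * d[1L]))^2 + (y - (p1[2L] + t * d[2L]))^2)
}

#' Per-synapse ultrastructural metrics
#'
#' Counts synaptic vesicles (excluding dense-core vesicles), records the
#' presynaptic area and mean vesicle diameter, classifies a vesicle as
#' docked when its membrane lies within `docked_gap_nm` of the
#' active-zone segment (center-to-segment distance minus radius), and
#' flags the presence of dense-core vesicles.
#'
#' @param map a [vesicle_map()].
#' @param docked_gap_nm docking criterion: maximum membrane-to-active-
#'   zone gap, nm (default 2).
#' @return A one-row data.frame with `synapse_id`, `sv_count`,
#'   `presyn_area_um2`, `mean_sv_diameter_nm`, `docked_pct`, `has_dcv`.
#' @export
synapse_metrics <- function(map, docked_gap_nm = 2) {
  stopifnot(inherits(map, "vesicle_map"))
  sv <- map$vesicles[!map$vesicles$is_dcv, , drop = FALSE]
  n <- nrow(sv)
  docked_pct <- NA_real_
  if (n > 0) {
    gap <- point_segment_distance(sv$x_nm, sv$y_nm, map$active_zone) -
      sv$diameter_nm / 2
    docked_pct <- 100 * sum(gap <= docked_gap_nm) / n
  }
  data.frame(synapse_id = map$synapse_id,
             sv_count = n,
             presyn_area_um2 = map$presyn_area,
             mean_sv_diameter_nm = if (n > 0) mean(sv$diameter_nm) else NA_real_,
             docked_pct = docked_pct,
             has_dcv = any(map$vesicles$is_dcv))
}

#' Nearest-neighbor analysis of a vesicle map
#'
#' For every synaptic vesicle (dense-core vesicles excluded), the
#' Euclidean center-to-center distance to the closest other synaptic
#' vesicle, summarized by the per-synapse empirical cumulative frequency
#' on a fixed distance grid and the per-synapse mean nearest-neighbor
#' distance.
#'
#' @param map a [vesicle_map()] with at least 2 synaptic vesicles.
#' @param grid_max upper bound of the ECDF grid, nm (default 200).
#' @param grid_step ECDF grid step, nm (default 1).
#' @return An object of class `nn_result` with `nn_distances` (nm, one
#'   per vesicle), `ecdf_grid`, `ecdf` and `mean_nn`.
#' @export
nn_analysis <- function(map, grid_max = 200, grid_step = 1) {
  stopifnot(inherits(map, "vesicle_map"))
  sv <- map$vesicles[!map$vesicles$is_dcv, , drop = FALSE]
  n <- nrow(sv)
  if (n < 2L) stop("nearest-neighbor analysis needs at least 2 synaptic vesicles")
  dm <- as.matrix(stats::dist(cbind(sv$x_nm, sv$y_nm)))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  grid <- seq(0, grid_max, by = grid_step)
  ec <- vapply(grid, function(g) mean(nn <= g), numeric(1L))
  structure(list(synapse_id = map$synapse_id, nn_distances = unname(nn),
                 ecdf_grid = grid, ecdf = ec, mean_nn = mean(nn)),
            class = "nn_result")
}

#' Group summary of nearest-neighbor results
#'
#' Averages the per-synapse cumulative frequency curves pointwise and
#' summarizes the group by the unweighted mean of the per-synapse mean
#' nearest-neighbor distances (every synapse counts equally, regardless
#' of its vesicle count).
#'
#' @param results list of `nn_result` objects from [nn_analysis()].
#' @return A list with `mean_ecdf` (data.frame `distance_nm`,
#'   `mean_cumfreq`), `group_mean_nn` and `per_synapse_mean_nn`.
#' @export
group_nn_summary <- function(results) {
  if (length(results) < 1L) stop("need at least 1 synapse")
  stopifnot(all(vapply(results, inherits, logical(1L), "nn_result")))
  grid <- results[[1L]]$ecdf_grid
  mat <- vapply(results, function(r) {
    if (!identical(r$ecdf_grid, grid)) stop("ECDF grids differ across synapses")
    r$ecdf
  }, numeric(length(grid)))
  per_syn <- vapply(results, `[[`, numeric(1L), "mean_nn")
  list(mean_ecdf = data.frame(distance_nm = grid,
                              mean_cumfreq = rowMeans(mat)),
       group_mean_nn = mean(per_syn),
       per_synapse_mean_nn = per_syn)
}

#' Synapse density of a micrograph field
#'
#' @param centroids data.frame or matrix of synapse centroid coordinates
#'   (one row per synapse; may have zero rows).
#' @param field_area field area, um^2 (must be positive).
#' @return Synapse density, synapses/um^2.
#' @export
synapse_density <- function(centroids, field_area) {
  if (field_area <= 0) stop("field_area must be > 0")
  NROW(centroids) / field_area
}
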