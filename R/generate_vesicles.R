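#' Construct a vesicle map
#'
#' Per-synapse container for 2-D vesicle coordinates (nm), diameters,
#' dense-core flags, the active-zone segment and the synapse-level
#' annotations used by the ultrastructure module.
#'
#' @param vesicles data.frame with columns `vesicle_id`, `x_nm`, `y_nm`,
#'   `diameter_nm`, `is_dcv`.
#' @param active_zone numeric length-4 vector `(x1, y1, x2, y2)` of the
#'   active-zone segment endpoints, nm.
#' @param presyn_area presynaptic terminal area, um^2.
#' @param psd_defined logical; is a postsynaptic density visible?
#' @param synapse_id identifier.
#' @param meta optional list of generator metadata.
#' @return An object of class `vesicle_map`.
#' @export
vesicle_map <- function(vesicles, active_zone, presyn_area,
                        psd_defined = TRUE, synapse_id = "syn1",
                        meta = list()) {
  need <- c("vesicle_id", "x_nm", "y_nm", "diameter_nm", "is_dcv")
  if (!all(need %in% names(vesicles)))
    stop("'vesicles' must have columns ", paste(need, collapse = ", "))
  if (length(active_zone) != 4L || !all(is.finite(active_zone)))
    stop("'active_zone' must be 4 finite numbers (x1, y1, x2, y2)")
  if (all(active_zone[1:2] == active_zone[3:4]))
    stop("active-zone endpoints must be distinct")
  if (any(!is.finite(vesicles$x_nm)) || any(!is.finite(vesicles$y_nm)))
    stop("vesicle coordinates must be finite")
  if (any(vesicles$diameter_nm <= 0))
    stop("vesicle diameters must be positive")
  structure(
    list(synapse_id = synapse_id, vesicles = vesicles,
         active_zone = as.numeric(active_zone),
         presyn_area = presyn_area, psd_defined = isTRUE(psd_defined),
         meta = meta),
    class = "vesicle_map"
  )
}

#' @export
print.vesicle_map <- function(x, ...) {
  cat(sprintf("<vesicle_map> %s: %d SVs + %d DCVs, AZ %.0f nm, area %.3f um^2, PSD %s\n",
              x$synapse_id, sum(!x$vesicles$is_dcv), sum(x$vesicles$is_dcv),
              sqrt(sum((x$active_zone[3:4] - x$active_zone[1:2])^2)),
              x$presyn_area, if (x$psd_defined) "defined" else "absent"))
  invisible(x)
}

# sequential hard-core placement: Gaussian cluster, minimum center-to-center
# distance `hard_core`, vertical clearance `y_min` above the AZ line
place_clustered <- function(n, center, sd, hard_core, y_min,
                            existing = NULL, max_try = 2000L) {
  pts <- existing
  out <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_try)) {
      cand <- stats::rnorm(2L, mean = center, sd = sd)
      if (cand[2L] < y_min) next
      if (!is.null(pts) && nrow(pts) > 0 &&
          min((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2) <
            hard_core^2) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("hard-core packing infeasible after ", max_try,
           " retries; increase cluster_sd")
    out[i, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

#' Generate a synthetic presynaptic vesicle map
#'
#' Draws the synaptic-vesicle count from a negative binomial
#' (mean `mean_sv_count`, size `count_dispersion`), places a docked
#' subpopulation along the active-zone segment with membrane gaps below
#' 2 nm, scatters the remainder as an isotropic Gaussian cluster centered
#' above the active zone, enforces a hard-core exclusion at one mean
#' vesicle diameter between all vesicle centers, and adds dense-core
#' vesicles with probability `dcv_prob`.
#'
#' @param preset a [vesicle_preset()].
#' @param seed integer seed.
#' @param synapse_id identifier for the generated synapse.
#' @param psd_prob probability that the synapse has a defined PSD
#'   (default 1).
#' @return A [vesicle_map()] with ground truth in `meta`.
#' @export
generate_vesicle_map <- function(preset, seed = NULL, synapse_id = "syn1",
                                 psd_prob = 1) {
  stopifnot(inherits(preset, "vesicle_preset"))
  if (!is.null(seed)) set.seed(seed)
  p <- preset

  n_sv <- stats::rnbinom(1L, size = p$count_dispersion, mu = p$mean_sv_count)
  # the docked row cannot exceed the hard-core capacity of the active zone
  n_docked <- min(round(p$docked_fraction_true * n_sv),
                  floor((p$az_length - p$sv_diameter_mean) /
                          p$sv_diameter_mean))
  n_free <- n_sv - n_docked
  hc <- p$sv_diameter_mean
  diam <- pmax(stats::rnorm(n_sv, p$sv_diameter_mean, p$sv_diameter_sd), 10)

  az <- c(-p$az_length / 2, 0, p$az_length / 2, 0)
  ctr <- c(0, 0.6 * p$cluster_sd)

  pts <- NULL
  if (n_docked > 0) {
    # docked: stratified along the AZ (one per bin, jittered within the
    # slack left by the hard core), membrane gap < 2 nm
    usable <- p$az_length - hc
    bin <- usable / n_docked
    if (bin < hc)
      stop("hard-core packing infeasible for docked vesicles; ",
           "reduce docked_fraction_true or increase az_length")
    slack <- (bin - hc) / 2
    xs <- az[1L] + hc / 2 + (seq_len(n_docked) - 0.5) * bin +
      stats::runif(n_docked, -slack, slack)
    ys <- diam[seq_len(n_docked)] / 2 + stats::runif(n_docked, 0, 2)
    pts <- cbind(xs, ys)
  }
  if (n_free > 0) {
    # clearance keeps non-docked membranes > 2 nm off the AZ line
    free <- place_clustered(n_free, ctr, p$cluster_sd, hc,
                            y_min = max(diam) / 2 + 2.5, existing = pts)
    pts <- rbind(pts, free)
  }

  n_dcv <- if (stats::runif(1L) < p$dcv_prob) 1L + stats::rpois(1L, 0.5) else 0L
  if (n_dcv > 0) {
    dcv_diam <- pmax(stats::rnorm(n_dcv, 2 * p$sv_diameter_mean,
                                  2 * p$sv_diameter_sd), 20)
    dcv_pts <- place_clustered(n_dcv, ctr, 1.2 * p$cluster_sd,
                               hc, y_min = max(dcv_diam) / 2 + 2.5,
                               existing = pts)
    pts <- rbind(pts, dcv_pts)
    diam <- c(diam, dcv_diam)
  }

  n_tot <- n_sv + n_dcv
  ves <- data.frame(
    vesicle_id = seq_len(n_tot),
    x_nm = if (n_tot > 0) pts[, 1L] else numeric(0),
    y_nm = if (n_tot > 0) pts[, 2L] else numeric(0),
    diameter_nm = diam[seq_len(n_tot)],
    is_dcv = rep(c(FALSE, TRUE), c(n_sv, n_dcv))
  )
  area <- max(stats::rnorm(1L, p$presyn_area_mean, 0.15 * p$presyn_area_mean),
              0.05)
  psd <- stats::runif(1L) < psd_prob

  vesicle_map(ves, active_zone = az, presyn_area = area, psd_defined = psd,
              synapse_id = synapse_id,
              meta = list(preset = unclass(p), seed = seed,
                          true_sv_count = n_sv, true_docked = n_docked,
                          true_dcv_count = n_dcv))
}
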