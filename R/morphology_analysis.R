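# segment table of a morphology: one row per (parent, child) dendritic pair
morph_segments <- function(m, compartment = c("all", "basal", "apical")) {
  compartment <- match.arg(compartment)
  nd <- m$nodes
  want_type <- switch(compartment, all = c(3L, 4L), basal = 3L, apical = 4L)
  child <- nd[nd$parent != -1 & nd$type %in% want_type, , drop = FALSE]
  if (nrow(child) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0)))
  par <- nd[match(child$parent, nd$id), , drop = FALSE]
  data.frame(x1 = par$x, y1 = par$y, z1 = par$z,
             x2 = child$x, y2 = child$y, z2 = child$z)
}

#' Sholl analysis
#'
#' Counts intersections of the dendritic arbor with concentric spheres
#' centered at the soma centroid. Each segment contributes one
#' intersection per sphere its interior crosses; a node lying exactly on
#' a sphere is counted once, with the crossing assigned to the segment
#' leaving it.
#'
#' @param m a [neuron_morphology()].
#' @param step sphere spacing, um (default 10).
#' @param compartment `"all"`, `"basal"` or `"apical"`.
#' @param max_radius outermost radius, um; defaults to the largest node
#'   distance rounded up to a multiple of `step`.
#' @param projection if `TRUE`, analyze the 2-D (x, y) projection with
#'   circles instead of spheres.
#' @return An object of class `sholl_result`: data.frame with columns
#'   `radius_um` and `intersections`.
#' @export
sholl <- function(m, step = 10, compartment = c("all", "basal", "apical"),
                  max_radius = NULL, projection = FALSE) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (step <= 0) stop("'step' must be positive")
  compartment <- match.arg(compartment)
  soma <- m$nodes[m$nodes$type == 1L, , drop = FALSE]
  ctr <- c(mean(soma$x), mean(soma$y), if (projection) 0 else mean(soma$z))
  segs <- morph_segments(m, compartment)
  if (projection && nrow(segs) > 0) segs$z1 <- segs$z2 <- 0

  all_d <- if (nrow(segs) > 0)
    sqrt(pmax((segs$x2 - ctr[1L])^2 + (segs$y2 - ctr[2L])^2 +
                (segs$z2 - ctr[3L])^2, 0)) else 0
  if (is.null(max_radius))
    max_radius <- max(step, ceiling(max(all_d) / step) * step)
  radii <- seq(step, max_radius, by = step)
  counts <- integer(length(radii))

  if (nrow(segs) > 0) {
    a <- cbind(segs$x1 - ctr[1L], segs$y1 - ctr[2L], segs$z1 - ctr[3L])
    b <- cbind(segs$x2 - segs$x1, segs$y2 - segs$y1, segs$z2 - segs$z1)
    bb <- rowSums(b^2)
    ab <- rowSums(a * b)
    aa <- rowSums(a^2)
    for (k in seq_along(radii)) {
      r <- radii[k]
      # |a + t b|^2 = r^2 on t in [0, 1): bb t^2 + 2 ab t + (aa - r^2) = 0
      disc <- ab^2 - bb * (aa - r^2)
      ok <- disc > 0 & bb > 0
      nseg <- integer(nrow(segs))
      sq <- sqrt(pmax(disc[ok], 0))
      t1 <- (-ab[ok] - sq) / bb[ok]
      t2 <- (-ab[ok] + sq) / bb[ok]
      eps <- 1e-9
      nseg[ok] <- (t1 >= -eps & t1 < 1 - eps) + (t2 >= -eps & t2 < 1 - eps)
      counts[k] <- sum(nseg)
    }
  }
  structure(data.frame(radius_um = radii, intersections = counts),
            class = c("sholl_result", "data.frame"))
}

#' Branch metrics of a morphology
#'
#' @param m a [neuron_morphology()].
#' @return A list with `branch_points` (dendritic nodes with at least 2
#'   children), `n_primary` (dendrites leaving the soma),
#'   `total_length` (dendritic cable, um), `mean_dendrite_length`
#'   (total cable per primary dendrite, um) and `soma_area`
#'   (\eqn{\pi r^2} for a point soma, or the soma outline polygon area
#'   when several soma nodes are present), um^2.
#' @export
branch_metrics <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  nd <- m$nodes
  dend <- nd$type %in% c(3L, 4L)
  soma_ids <- nd$id[nd$type == 1L]
  child_counts <- table(nd$parent[dend])
  dend_ids <- nd$id[dend]
  bp <- sum(child_counts[names(child_counts) %in% as.character(dend_ids)] >= 2L)
  n_primary <- sum(nd$parent[dend] %in% soma_ids)

  segs <- morph_segments(m, "all")
  total_len <- if (nrow(segs) > 0)
    sum(sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2 +
               (segs$z2 - segs$z1)^2)) else 0

  soma <- nd[nd$type == 1L, , drop = FALSE]
  soma_area <- if (nrow(soma) == 1L) {
    pi * soma$radius^2
  } else {
    # shoelace area of the soma outline in the x-y plane
    x <- soma$x; y <- soma$y
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }
  list(branch_points = as.integer(bp), n_primary = as.integer(n_primary),
       total_length = total_len,
       mean_dendrite_length = if (n_primary > 0) total_len / n_primary
                              else NA_real_,
       soma_area = soma_area)
}

#' Classify a dendritic spine from its geometry
#'
#' Deterministic rule on head/neck ratio and length: mushroom when
#' `head_diam/neck_diam > 1.5` and `head_diam > 0.35` um; otherwise
#' stubby when `length/neck_diam < 1`; otherwise thin.
#'
#' @param length_um,head_diam_um,neck_diam_um spine geometry, um
#'   (vectorized).
#' @return Character vector of types in
#'   `c("stubby", "thin", "mushroom")`.
#' @export
classify_spine <- function(length_um, head_diam_um, neck_diam_um) {
  if (any(c(length_um, head_diam_um, neck_diam_um) <= 0))
    stop("spine geometry must be positive")
  ifelse(head_diam_um / neck_diam_um > 1.5 & head_diam_um > 0.35, "mushroom",
         ifelse(length_um / neck_diam_um < 1, "stubby", "thin"))
}

#' Spine density and type composition
#'
#' @param m a [neuron_morphology()]; its total dendritic cable length is
#'   the density denominator.
#' @param spines spine table (defaults to `m$spines`): columns
#'   `length_um`, `head_diam_um`, `neck_diam_um`.
#' @return A list with `density` (spines/um), `n_spines`,
#'   `type_fractions` (named, sums to 1 when spines are present) and the
#'   classified `types`.
#' @export
spine_metrics <- function(m, spines = NULL) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (is.null(spines)) spines <- m$spines
  total_len <- branch_metrics(m)$total_length
  if (total_len <= 0) stop("dendritic length must be positive")
  n <- NROW(spines)
  if (n == 0) {
    return(list(density = 0, n_spines = 0L,
                type_fractions = c(stubby = NA_real_, thin = NA_real_,
                                   mushroom = NA_real_),
                types = character(0)))
  }
  types <- classify_spine(spines$length_um, spines$head_diam_um,
                          spines$neck_diam_um)
  fr <- vapply(c("stubby", "thin", "mushroom"),
               function(tp) mean(types == tp), numeric(1L))
  list(density = n / total_len, n_spines = as.integer(n),
       type_fractions = fr, types = types)
}
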