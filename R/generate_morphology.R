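#' Construct a neuron morphology
#'
#' An SWC-style node table (one soma node plus dendritic nodes with
#' parent links) together with an optional spine table.
#'
#' @param nodes data.frame with SWC columns `id`, `type` (1 = soma,
#'   3 = basal dendrite, 4 = apical dendrite), `x`, `y`, `z` (um),
#'   `radius` (um), `parent` (-1 for the root).
#' @param spines data.frame with columns `id`, `attach_position_um`
#'   (arc-length position along the cable), `length_um`, `head_diam_um`,
#'   `neck_diam_um` and optionally `true_type`; may be `NULL`.
#' @param meta optional list of generator metadata (ground truth).
#' @return An object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes, spines = NULL, meta = list()) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("'nodes' must have SWC columns ", paste(need, collapse = ", "))
  if (sum(nodes$parent == -1) != 1L)
    stop("morphology must have exactly one root node")
  nonroot <- which(nodes$parent != -1)
  pidx <- match(nodes$parent[nonroot], nodes$id)
  if (anyNA(pidx))
    stop("every non-root parent id must exist")
  if (any(pidx >= nonroot))
    stop("parent nodes must precede their children")
  structure(list(nodes = nodes, spines = spines, meta = meta),
            class = "neuron_morphology")
}

#' @export
print.neuron_morphology <- function(x, ...) {
  bm <- branch_metrics(x)
  cat(sprintf("<neuron_morphology> %d nodes, %d branch points, total cable %.1f um, %d spines\n",
              nrow(x$nodes), bm$branch_points,
              bm$total_length, if (is.null(x$spines)) 0L else nrow(x$spines)))
  invisible(x)
}

#' Generate a stochastic dendritic tree with typed spines
#'
#' Grows `n_primary` dendrites from a point soma by recursive
#' bifurcation: each segment (length drawn around `segment_len_mean`)
#' either bifurcates with probability `branch_prob` or terminates, up to
#' `max_depth` segments from the soma. Spines are placed along the total
#' cable as a Poisson process at `spine_density_true`, with geometry
#' drawn from type-conditional distributions according to
#' `spine_type_probs`. Ground-truth branch-point count, cable length and
#' spine types are attached in `meta`.
#'
#' @param preset a [morph_preset()].
#' @param seed integer seed.
#' @return A [neuron_morphology()].
#' @export
generate_morphology <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "morph_preset"))
  if (!is.null(seed)) set.seed(seed)
  p <- preset

  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = p$soma_radius, parent = -1L))
  next_id <- 2L
  n_branch <- 0L
  total_len <- 0

  rand_dir <- function(dir, jitter_sd) {
    d <- dir + stats::rnorm(3L, 0, jitter_sd)
    d / sqrt(sum(d^2))
  }

  # stack of segments to grow: (parent id, origin, direction, depth)
  stack <- lapply(seq_len(p$n_primary), function(i) {
    ang <- 2 * pi * (i - 1) / p$n_primary
    dir <- c(cos(ang), sin(ang), stats::rnorm(1L, 0, 0.3))
    list(parent = 1L, origin = c(0, 0, 0), dir = dir / sqrt(sum(dir^2)),
         depth = 1L)
  })

  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    len <- max(stats::rlnorm(1L, log(p$segment_len_mean) - 0.02, 0.2), 1)
    dir <- rand_dir(seg$dir, 0.15)
    end <- seg$origin + len * dir
    id <- next_id; next_id <- next_id + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(id = id, type = 3L, x = end[1L], y = end[2L], z = end[3L],
                 radius = max(1.2 * 0.85^seg$depth, 0.2), parent = seg$parent)
    total_len <- total_len + len
    if (seg$depth < p$max_depth && stats::runif(1L) < p$branch_prob) {
      n_branch <- n_branch + 1L
      for (s in c(-1, 1)) {
        perp <- rand_dir(dir + s * 0.6 * c(-dir[2L], dir[1L], 0.3 * s), 0.1)
        stack[[length(stack) + 1L]] <-
          list(parent = id, origin = end, dir = perp, depth = seg$depth + 1L)
      }
    }
  }

  nodes <- do.call(rbind, rows)

  n_spines <- stats::rpois(1L, p$spine_density_true * total_len)
  spines <- NULL
  if (n_spines > 0) {
    type <- sample(c("stubby", "thin", "mushroom"), n_spines, replace = TRUE,
                   prob = p$spine_type_probs)
    geom <- t(vapply(type, spine_geometry_draw, numeric(3L)))
    spines <- data.frame(
      id = seq_len(n_spines),
      attach_position_um = sort(stats::runif(n_spines, 0, total_len)),
      length_um = geom[, 1L], head_diam_um = geom[, 2L],
      neck_diam_um = geom[, 3L], true_type = type,
      row.names = NULL
    )
  }

  neuron_morphology(nodes, spines,
                    meta = list(preset = unclass(p), seed = seed,
                                true_branch_points = n_branch,
                                true_total_length = total_len,
                                true_n_spines = n_spines))
}

# type-conditional spine geometry (length, head diameter, neck diameter), um.
# Distributions are concentrated enough that the deterministic classifier
# in classify_spine() recovers the generating type > 95% of the time.
spine_geometry_draw <- function(type) {
  draw <- function(mu, sd, lo) max(stats::rnorm(1L, mu, sd), lo)
  switch(type,
    stubby   = c(draw(0.35, 0.05, 0.1), draw(0.40, 0.05, 0.1),
                 draw(0.55, 0.05, 0.2)),
    thin     = c(draw(1.50, 0.30, 0.5), draw(0.20, 0.03, 0.05),
                 draw(0.15, 0.02, 0.05)),
    mushroom = c(draw(1.20, 0.25, 0.4), draw(0.65, 0.08, 0.40),
                 draw(0.25, 0.04, 0.10))
  )
}
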