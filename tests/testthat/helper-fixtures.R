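# shared in-code fixtures

# vesicle map with explicit coordinates (nm); AZ along y = 0
make_map <- function(xy, diam = 40, dcv = FALSE, psd = TRUE,
                     az = c(-250, 0, 250, 0), area = 0.35, id = "fix") {
  n <- nrow(xy)
  vesicle_map(
    data.frame(vesicle_id = seq_len(n), x_nm = xy[, 1], y_nm = xy[, 2],
               diameter_nm = rep_len(diam, n), is_dcv = rep_len(dcv, n)),
    active_zone = az, presyn_area = area, psd_defined = psd, synapse_id = id)
}

# random non-degenerate point set (no hard core; for NN oracle checks)
random_xy <- function(n, seed, range = 500) {
  set.seed(seed)
  cbind(runif(n, -range, range), runif(n, -range, range))
}

# straight neurite of `len` um along +x split into `nseg` SWC segments
straight_neurite <- function(len = 100, nseg = 10) {
  xs <- seq(0, len, length.out = nseg + 1)[-1]
  nodes <- rbind(
    data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0, radius = 5,
               parent = -1L),
    data.frame(id = seq_len(nseg) + 1L, type = 3L, x = xs, y = 0, z = 0,
               radius = 0.5, parent = seq_len(nseg)))
  neuron_morphology(nodes)
}

# Y-shaped tree: trunk 50 um then two 30 um arms (one primary dendrite)
y_tree <- function() {
  nodes <- data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 50, 50 + 30 / sqrt(2), 50 + 30 / sqrt(2)),
    y = c(0, 0, 30 / sqrt(2), -30 / sqrt(2)),
    z = 0, radius = c(5, 1, 0.5, 0.5), parent = c(-1L, 1L, 2L, 2L))
  neuron_morphology(nodes)
}

# brute-force nearest neighbor by explicit double loop
nn_bruteforce <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# brute-force sphere-segment intersection count by dense parameter scan:
# counts sign changes of (|p(t)| - r) over t in [0, 1) for every segment
sholl_bruteforce <- function(m, radii, center) {
  nd <- m$nodes
  child <- nd[nd$parent != -1 & nd$type %in% c(3L, 4L), , drop = FALSE]
  par <- nd[match(child$parent, nd$id), , drop = FALSE]
  counts <- integer(length(radii))
  ts <- seq(0, 1, length.out = 2001)
  for (s in seq_len(nrow(child))) {
    p1 <- c(par$x[s], par$y[s], par$z[s]) - center
    d <- c(child$x[s], child$y[s], child$z[s]) - center - p1
    dist_t <- sqrt(colSums((outer(p1, rep(1, length(ts))) + outer(d, ts))^2))
    for (k in seq_along(radii)) {
      f <- dist_t - radii[k]
      # crossings within [0, 1): sign changes between consecutive samples
      sgn <- sign(f)
      sgn[sgn == 0] <- 1e-12
      cross <- sum(f[-length(f)] * f[-1] < 0)
      # endpoint conventions: start exactly on sphere counts, end does not
      if (abs(f[1]) < 1e-9) cross <- cross + 1L
      if (abs(f[length(f)]) < 1e-9 && f[length(f) - 1] * f[length(f)] < 0)
        cross <- cross - 1L
      counts[k] <- counts[k] + cross
    }
  }
  counts
}
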