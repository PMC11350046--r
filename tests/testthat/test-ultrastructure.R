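test_that("synapse inclusion filter applies the boundary rules", {
  grid_xy <- function(n) cbind(60 * (seq_len(n) %% 20), 60 * (seq_len(n) %/% 20))
  m9 <- make_map(grid_xy(9)); m10 <- make_map(grid_xy(10))
  m250 <- make_map(grid_xy(250)); m251 <- make_map(grid_xy(251))
  m_nopsd <- make_map(grid_xy(100), psd = FALSE)
  kept <- filter_synapses(list(m9, m10, m250, m251, m_nopsd))
  expect_length(kept, 2)  # only the 10-SV and 250-SV maps survive
  expect_equal(vapply(kept, function(m) sum(!m$vesicles$is_dcv), numeric(1)),
               c(10, 250))

  # DCVs do not count toward the SV bounds
  m_dcv <- make_map(grid_xy(12), dcv = c(rep(FALSE, 9), rep(TRUE, 3)))
  expect_length(filter_synapses(list(m_dcv)), 0)
})

test_that("docked classification follows membrane-to-AZ geometry", {
  # radius 20 nm, center 21 nm above the AZ line: gap 1 nm <= 2 -> docked
  m <- make_map(cbind(c(0, 100), c(21, 100)), diam = 40)
  sm <- synapse_metrics(m)
  expect_equal(sm$docked_pct, 50)
  expect_false(sm$has_dcv)
  # gap 3 nm -> not docked
  m2 <- make_map(cbind(0, 23), diam = 40)
  expect_equal(synapse_metrics(m2)$docked_pct, 0)
})

test_that("docked percentage agrees with a point-segment oracle", {
  for (seed in 1:5) {
    xy <- random_xy(40, seed, range = 300)
    xy[, 2] <- abs(xy[, 2])
    m <- make_map(xy, diam = 40)
    sm <- synapse_metrics(m)
    az <- m$active_zone
    # brute-force point-to-segment distance
    gap <- vapply(seq_len(nrow(xy)), function(i) {
      p <- xy[i, ]
      t <- max(0, min(1, (p[1] - az[1]) / (az[3] - az[1])))
      proj <- c(az[1] + t * (az[3] - az[1]), 0)
      sqrt(sum((p - proj)^2)) - 20
    }, numeric(1))
    expect_equal(sm$docked_pct, 100 * mean(gap <= 2))
  }
})

test_that("nearest-neighbor distances match an O(n^2) oracle", {
  m <- make_map(cbind(c(0, 40), c(100, 100)))
  r <- nn_analysis(m)
  expect_equal(r$nn_distances, c(40, 40))
  expect_equal(r$mean_nn, 40)

  for (seed in 1:5) {
    xy <- random_xy(50, seed)
    r <- nn_analysis(make_map(xy))
    expect_equal(r$nn_distances, nn_bruteforce(xy), tolerance = 1e-12)
  }
  expect_error(nn_analysis(make_map(cbind(0, 0))), "at least 2")
})

test_that("NN analysis is invariant under rigid motions", {
  xy <- random_xy(60, 4)
  r1 <- nn_analysis(make_map(xy))
  th <- 0.7
  rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(rot, 2, c(123, -45), "+")
  r2 <- nn_analysis(make_map(rot))
  expect_equal(sort(r2$nn_distances), sort(r1$nn_distances),
               tolerance = 1e-9)
  expect_equal(r2$mean_nn, r1$mean_nn, tolerance = 1e-9)
})

test_that("DCVs are excluded from counts and NN analysis", {
  xy <- rbind(cbind(c(0, 50, 100), 100), c(50, 150))
  m <- make_map(xy, dcv = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(synapse_metrics(m)$sv_count, 3)
  expect_true(synapse_metrics(m)$has_dcv)
  r <- nn_analysis(m)
  expect_length(r$nn_distances, 3)
  expect_equal(r$nn_distances, c(50, 50, 50))
})

test_that("group summary averages per synapse, not per vesicle", {
  # identical synapses: mean ECDF equals each ECDF
  xy <- random_xy(30, 8)
  r <- nn_analysis(make_map(xy))
  g <- group_nn_summary(list(r, r, r))
  expect_equal(g$mean_ecdf$mean_cumfreq, r$ecdf)
  expect_equal(g$group_mean_nn, r$mean_nn)

  # unbalanced counts: unweighted per-synapse mean differs from the
  # vesicle-weighted pooled mean, and the implementation uses the former
  big <- nn_analysis(make_map(random_xy(200, 9, range = 2000)))
  small <- nn_analysis(make_map(cbind(c(0, 10), c(0, 0))))
  g2 <- group_nn_summary(list(big, small))
  unweighted <- mean(c(big$mean_nn, small$mean_nn))
  pooled <- mean(c(big$nn_distances, small$nn_distances))
  expect_equal(g2$group_mean_nn, unweighted)
  expect_gt(abs(unweighted - pooled), 1)

  # averaging ECDFs then reading the median is not the pooled median
  mean_ec <- g2$mean_ecdf
  med_avg <- mean_ec$distance_nm[which(mean_ec$mean_cumfreq >= 0.5)[1]]
  med_pool <- stats::median(c(big$nn_distances, small$nn_distances))
  expect_gt(abs(med_avg - med_pool), 1)
})

test_that("synapse density is count over area", {
  expect_equal(synapse_density(matrix(0, 10, 2), 100), 0.1)
  expect_equal(synapse_density(matrix(numeric(0), 0, 2), 50), 0)
  cents <- random_xy(25, 3)
  expect_equal(synapse_density(cents, 12.5), 2)
  expect_error(synapse_density(cents, 0), "field_area")
})

test_that("generated maps respect the hard core for every seed", {
  pre <- default_vesicle_preset("WT", "4mo")
  for (i in 1:60) {
    m <- generate_vesicle_map(pre, seed = 1000 + i)
    xy <- cbind(m$vesicles$x_nm, m$vesicles$y_nm)
    if (nrow(xy) < 2) next
    expect_gte(min(stats::dist(xy)), pre$sv_diameter_mean)
  }
})

test_that("generated maps are reproducible and carry ground truth", {
  pre <- default_vesicle_preset("Tau35", "10mo")
  a <- generate_vesicle_map(pre, seed = 5)
  b <- generate_vesicle_map(pre, seed = 5)
  expect_identical(a$vesicles, b$vesicles)
  expect_equal(sum(!a$vesicles$is_dcv), a$meta$true_sv_count)
  expect_equal(sum(a$vesicles$is_dcv), a$meta$true_dcv_count)
})
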