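test_that("Sholl profile of a straight neurite", {
  m <- straight_neurite(100, nseg = 10)
  r <- sholl(m, step = 10)
  expect_equal(r$radius_um, seq(10, 100, by = 10))
  # one crossing at 10..90; the tip sits exactly on 100: no strict crossing
  expect_equal(r$intersections, c(rep(1L, 9), 0L))
})

test_that("Sholl matches a brute-force sphere-segment oracle", {
  for (seed in c(2, 5, 9)) {
    m <- generate_morphology(default_morph_preset("WT"), seed = seed)
    r <- sholl(m, step = 10)
    soma <- m$nodes[m$nodes$type == 1L, ]
    oracle <- sholl_bruteforce(m, r$radius_um,
                               c(soma$x, soma$y, soma$z))
    expect_equal(r$intersections, oracle)
  }
})

test_that("Sholl is invariant under rigid transforms", {
  m <- generate_morphology(default_morph_preset("Tau35"), seed = 3)
  r1 <- sholl(m, step = 10, max_radius = 150)
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% R
  m2 <- m
  m2$nodes$x <- xyz[, 1] + 40
  m2$nodes$y <- xyz[, 2] - 15
  m2$nodes$z <- xyz[, 3] + 3
  r2 <- sholl(m2, step = 10, max_radius = 150)
  expect_equal(r2$intersections, r1$intersections)
})

test_that("crossings exceed the primary count for multi-step trees", {
  m <- generate_morphology(default_morph_preset("WT"), seed = 12)
  r <- sholl(m, step = 10)
  expect_gte(sum(r$intersections), branch_metrics(m)$n_primary)
})

test_that("branch metrics on hand-built trees", {
  m <- straight_neurite(100)
  bm <- branch_metrics(m)
  expect_equal(bm$branch_points, 0L)
  expect_equal(bm$total_length, 100)

  y <- y_tree()
  bm <- branch_metrics(y)
  expect_equal(bm$branch_points, 1L)
  expect_equal(bm$n_primary, 1L)
  expect_equal(bm$mean_dendrite_length, 110)
  expect_equal(bm$soma_area, pi * 25)
})

test_that("generated branch counts equal the ground-truth labels", {
  for (geno in c("WT", "Tau35")) {
    pre <- default_morph_preset(geno)
    for (i in 1:50) {
      m <- generate_morphology(pre, seed = 400 + i)
      expect_identical(branch_metrics(m)$branch_points,
                       m$meta$true_branch_points)
      expect_equal(branch_metrics(m)$total_length,
                   m$meta$true_total_length, tolerance = 1e-9)
    }
  }
})

test_that("spine density is count per unit cable", {
  m <- straight_neurite(20)
  spines <- data.frame(id = 1:10, attach_position_um = seq(1, 19, 2),
                       length_um = 1.2, head_diam_um = 0.6,
                       neck_diam_um = 0.2)
  sm <- spine_metrics(m, spines)
  expect_equal(sm$density, 0.5)
  expect_equal(sum(sm$type_fractions), 1)
})

test_that("spine classification rule is deterministic", {
  expect_equal(classify_spine(1.0, 0.6, 0.2), "mushroom")
  expect_equal(classify_spine(0.3, 0.3, 0.4), "stubby")
  expect_equal(classify_spine(1.5, 0.2, 0.15), "thin")
  expect_equal(classify_spine(c(1, 0.3), c(0.6, 0.3), c(0.2, 0.4)),
               c("mushroom", "stubby"))
  expect_error(classify_spine(0, 0.3, 0.2), "positive")
})

test_that("classification recovers generated spine types", {
  hits <- 0; total <- 0
  for (i in 1:30) {
    m <- generate_morphology(default_morph_preset("WT"), seed = 800 + i)
    if (is.null(m$spines)) next
    types <- classify_spine(m$spines$length_um, m$spines$head_diam_um,
                            m$spines$neck_diam_um)
    hits <- hits + sum(types == m$spines$true_type)
    total <- total + nrow(m$spines)
  }
  expect_gte(hits / total, 0.95)
})

test_that("measured spine density recovers the generating density", {
  dens <- vapply(1:50, function(i) {
    m <- generate_morphology(default_morph_preset("WT"), seed = 1200 + i)
    spine_metrics(m)$density
  }, numeric(1))
  true <- default_morph_preset("WT")$spine_density_true
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - true), 3 * se + 1e-6)
})

test_that("SWC validity rules are enforced", {
  nodes <- data.frame(id = 1:2, type = c(1L, 3L), x = 0, y = 0, z = 0,
                      radius = 1, parent = c(-1L, 5L))
  expect_error(neuron_morphology(nodes), "parent id")
  nodes2 <- data.frame(id = 1:2, type = c(1L, 1L), x = 0, y = 0, z = 0,
                       radius = 1, parent = c(-1L, -1L))
  expect_error(neuron_morphology(nodes2), "one root")
})
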