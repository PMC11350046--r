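test_that("t test handles identity, separation and degenerate input", {
  r <- group_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r2 <- group_t_test(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(r2$p, 0.001)

  r3 <- group_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r3$p, 1)
  expect_error(group_t_test(1, c(1, 2)), "at least 2")
})

test_that("t test holds its nominal type-I error rate", {
  set.seed(1)
  p <- vapply(1:10000, function(i)
    group_t_test(rnorm(8), rnorm(8))$p, numeric(1))
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.2)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("t test agrees with a permutation test on small samples", {
  set.seed(7)
  a <- rnorm(6, 0.8); b <- rnorm(7)
  r <- group_t_test(a, b)
  pool <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  perm <- vapply(1:20000, function(i) {
    idx <- sample(length(pool), n)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_equal(r$p, p_perm, tolerance = 0.25)
})

test_that("star annotation is a pure function of p", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(c(0.05, 0.01, 0.001, 1e-4)),
               c("ns", "*", "**", "***"))  # strict thresholds
  expect_error(p_stars(1.2), "\\[0, 1\\]")
})

test_that("percent change is scale invariant", {
  expect_equal(percent_change(2.0, 0.46), -77)
  expect_equal(percent_change(2000, 460), -77)
  expect_error(percent_change(0, 1), "zero")
})

test_that("two-way ANOVA p values are uniform under the null", {
  set.seed(3)
  ps <- vapply(1:400, function(i) {
    tab <- data.frame(y = rnorm(24),
                      g = rep(c("a", "b"), each = 12),
                      t = rep(c("x", "y"), 12))
    anova2_tukey(tab, c("g", "t"), "y")$anova$p
  }, numeric(3))
  for (k in 1:3) {
    ks <- suppressWarnings(stats::ks.test(ps[k, ], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("two-way ANOVA detects an additive construction", {
  set.seed(5)
  tab <- expand.grid(g = c("WT", "Tau35"), t = c("4mo", "10mo"),
                     rep = 1:10)
  tab$y <- rnorm(nrow(tab), sd = 0.5) + ifelse(tab$g == "Tau35", -3, 0) +
    ifelse(tab$t == "10mo", 1.5, 0)
  r <- anova2_tukey(tab, c("g", "t"), "y")
  expect_lt(r$anova$p[1], 0.001)
  expect_lt(r$anova$p[2], 0.001)
  expect_gt(r$anova$p[3], 0.05)  # no interaction built in
  expect_equal(nrow(r$tukey), 6)  # all pairwise cell comparisons
})

test_that("empty design cells are named in the error", {
  tab <- data.frame(y = rnorm(6), g = c("a", "a", "a", "b", "b", "b"),
                    t = c("x", "x", "x", "x", "x", "y"))
  expect_error(anova2_tukey(tab, c("g", "t"), "y"), "empty design cell.*a")
})
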