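test_that("noiseless inserted kernels are all detected, no extras", {
  pre <- sepsc_preset(rate = 5 / 30, noise_sd = 0, duration = 30)
  g <- generate_sepsc_trace(pre, seed = 11)
  n_true <- length(g$ground_truth)
  ev <- detect_events(g$trace)
  expect_equal(nrow(ev), n_true)
  st <- waveform_stats(average_events(g$trace, ev), ev)
  expect_equal(st$frequency, n_true / 30)
})

test_that("false positives on noise-only traces are rare", {
  # default threshold calibration: <= 1 false positive per 30 s trace
  fp <- vapply(1:40, function(i) {
    g <- generate_sepsc_trace(sepsc_preset(rate = 0, duration = 30),
                              seed = 5000 + i)
    nrow(detect_events(g$trace))
  }, numeric(1))
  expect_lte(mean(fp), 1)
})

test_that("detection is sensitive at SNR 10 against ground truth", {
  hits <- 0; total <- 0
  for (i in 1:8) {
    g <- generate_sepsc_trace(default_sepsc_preset("WT"), seed = 700 + i)
    det <- detect_events(g$trace)$time_ms
    total <- total + length(g$ground_truth)
    hits <- hits + sum(vapply(g$ground_truth,
                              function(t) any(abs(det - t) <= 2),
                              logical(1)))
  }
  expect_gte(hits / total, 0.95)
})

test_that("detection is equivariant to constant offsets", {
  g <- generate_sepsc_trace(default_sepsc_preset("WT", duration = 10),
                            seed = 21)
  ev <- detect_events(g$trace)
  shifted <- g$trace
  shifted$samples <- shifted$samples - 35  # holding-current offset
  ev2 <- detect_events(shifted)
  expect_equal(ev2$time_ms, ev$time_ms)
  expect_equal(ev2$scale_pA, ev$scale_pA, tolerance = 1e-8)
})

test_that("template and trace must be compatible", {
  g <- generate_sepsc_trace(sepsc_preset(duration = 0.02), seed = 1)
  tpl <- sepsc_template(dt = 0.1, length_ms = 100)
  expect_error(detect_events(g$trace, tpl), "longer than trace")
  expect_error(detect_events(g$trace, sepsc_template(dt = 0.2)), "dt")
})

test_that("averaging identical noiseless events reproduces the kernel", {
  pre <- sepsc_preset(rate = 10 / 30, noise_sd = 0, duration = 30)
  g <- generate_sepsc_trace(pre, seed = 31)
  ev <- detect_events(g$trace)
  avg <- average_events(g$trace, ev)
  # compare to the analytic kernel aligned at the detection point
  kern <- biexp_kernel(avg$t_ms, pre$amp, pre$tau_rise, pre$tau_decay)
  expect_lt(max(abs(avg$mean - kern)), 0.15)
})

test_that("averaging attenuates noise roughly as 1/sqrt(N)", {
  dt <- 0.1
  rel_len <- 501
  set.seed(99)
  noise_sd <- 2
  # N noisy copies of the same kernel
  N <- 100
  kern <- biexp_kernel((0:(rel_len - 1)) * dt, -20, 0.8, 4)
  resid_sd <- {
    snips <- replicate(N, kern + rnorm(rel_len, 0, noise_sd))
    sd(rowMeans(snips) - kern)
  }
  expect_equal(resid_sd, noise_sd / sqrt(N), tolerance = 0.2)
})

test_that("waveform statistics match analytic kernel properties", {
  # single clean event: amplitude, half-width against root-finding oracle
  dt <- 0.1
  tau_r <- 0.8; tau_d <- 4; amp <- -20
  kern <- biexp_kernel((0:1000) * dt, amp, tau_r, tau_d)
  y <- c(rep(0, 500), kern)
  tr <- ephys_trace(y, dt = dt, unit = "pA")
  ev <- structure(data.frame(time_ms = 50, scale_pA = amp, criterion = 10),
                  class = c("event_list", "data.frame"))
  st <- waveform_stats(average_events(tr, ev), ev, duration_s = 30)
  expect_equal(st$frequency, 1 / 30)
  expect_equal(st$amplitude, 20, tolerance = 1e-3)  # absolute value

  # oracle: continuous half-width by root finding on the kernel formula
  t_pk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  f <- function(t) biexp_kernel(t, amp, tau_r, tau_d) - amp / 2
  hw_oracle <- uniroot(f, c(t_pk, 100))$root - uniroot(f, c(0, t_pk))$root
  expect_equal(st$half_width, hw_oracle, tolerance = 0.01)
  expect_gt(st$rate_of_rise, 0)

  # 15 events in 30 s give 0.5 Hz
  ev15 <- structure(data.frame(time_ms = seq(100, 1500, by = 100),
                               scale_pA = amp, criterion = 10),
                    class = c("event_list", "data.frame"))
  expect_equal(waveform_stats(NULL, ev15, duration_s = 30)$frequency, 0.5)
})
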