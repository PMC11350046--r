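iv_protocol <- step_protocol(holding_target = -90, step_amp = -90,
                             onset = 10, duration = 30,
                             n_steps = 12, step_increment = 10)
iv_volts <- seq(-90, 20, by = 10)

test_that("Boltzmann parameters are recovered from clean currents", {
  Cm <- 100
  G <- 0.5 / (1 + exp(-(iv_volts - (-30)) / 8))
  iss <- 2 * (iv_volts - (-70)) + G * 100 * Cm  # ohmic leak + channel
  r <- analyze_iv(iss, iv_protocol, C_m_est = Cm)
  expect_false(r$flagged)
  # the leak estimate absorbs the (tiny) channel conductance still open
  # at -90/-80 mV, so recovery is near-exact rather than bitwise
  expect_equal(r$G_max, 0.5, tolerance = 0.02)
  expect_equal(r$V_half, -30, tolerance = 0.01)
  expect_equal(r$slope_k, 8, tolerance = 0.03)
})

test_that("Boltzmann fit is scale equivariant", {
  Cm <- 80
  G <- 0.4 / (1 + exp(-(iv_volts + 25) / 6))
  iss <- 1.5 * (iv_volts + 65) + G * 100 * Cm
  r1 <- analyze_iv(iss, iv_protocol, C_m_est = Cm)
  r3 <- analyze_iv(iss * 3, iv_protocol, C_m_est = Cm)
  expect_equal(r3$G_max / r1$G_max, 3, tolerance = 1e-6)
  expect_equal(r3$V_half, r1$V_half, tolerance = 1e-6)
  expect_equal(r3$slope_k, r1$slope_k, tolerance = 1e-6)
})

test_that("pure ohmic input is leak-subtracted to zero and flagged", {
  iss <- 2 * (iv_volts + 70)
  r <- analyze_iv(iss, iv_protocol, C_m_est = 100)
  expect_true(r$flagged)
  expect_equal(max(abs(r$specific_currents)), 0, tolerance = 1e-9)
})

test_that("V_half recovery is robust to multiplicative noise", {
  set.seed(11)
  Cm <- 100
  G <- 0.5 / (1 + exp(-(iv_volts + 30) / 8))
  base <- 2 * (iv_volts + 70) + G * 100 * Cm
  err <- vapply(1:100, function(i) {
    iss <- base * (1 + rnorm(length(base), 0, 0.05))
    r <- analyze_iv(iss, iv_protocol, C_m_est = Cm)
    abs(r$V_half + 30)
  }, numeric(1))
  expect_lt(median(err), 2)
})

test_that("physical driving-force variant changes G accordingly", {
  Cm <- 100
  iss <- 2 * (iv_volts + 70) + 50 * Cm  # constant extra current
  r_fix <- analyze_iv(iss, iv_protocol, C_m_est = Cm, driving = "fixed")
  r_phys <- analyze_iv(iss, iv_protocol, C_m_est = Cm,
                       driving = "physical", E_K = -100)
  i_spec <- r_fix$specific_currents
  expect_equal(r_fix$G, i_spec / 100)
  expect_equal(r_phys$G, i_spec / (iv_volts + 100))
})

test_that("usable-step and capacitance preconditions hold", {
  expect_error(analyze_iv(1:3, iv_protocol, C_m_est = 100), "4 usable")
  expect_error(analyze_iv(1:12, iv_protocol, C_m_est = 0), "C_m_est")
})

test_that("AP waveform metrics match closed forms on a Gaussian spike", {
  proto <- step_protocol(step_amp = 300, onset = 100, duration = 500)
  dt <- 0.05
  tt <- seq(0, 800, by = dt)
  sigma <- 1
  v <- -65 + 80 * exp(-((tt - 300) / sigma)^2)
  tr <- ephys_trace(v, dt = dt, unit = "mV", protocol = proto)
  ap <- analyze_ap(tr)
  expect_equal(ap$n_spikes, 1L)
  expect_equal(ap$peak, 15, tolerance = 1e-3)
  # width: time above (threshold + peak)/2, from the Gaussian closed form
  half_level <- (ap$threshold + ap$peak) / 2
  w_analytic <- 2 * sigma * sqrt(log(80 / (half_level + 65)))
  expect_equal(ap$width, w_analytic, tolerance = 0.05)
  # max rise against a centered-difference oracle on the same samples
  dvdt_oracle <- max((v[-1] - v[-length(v)]) / dt)
  expect_equal(ap$max_rise, dvdt_oracle, tolerance = 1e-9)

  flat <- ephys_trace(rep(-65, 1000), dt = dt, unit = "mV",
                      protocol = proto)
  expect_equal(analyze_ap(flat)$n_spikes, 0L)
})
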