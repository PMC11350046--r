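#' Simulate a single-compartment neuron under a current step
#'
#' Integrates the membrane equation
#' \deqn{C_m dV/dt = -g_L (V - E_L) - g_h m (V - E_h) - g_K n (V - E_{K}) + I(t)}
#' with first-order gating
#' \deqn{dm/dt = (m_\infty(V) - m)/\tau_h, \quad
#'       m_\infty(V) = 1/(1 + \exp((V - V_{1/2,h})/k_h)),}
#' so the h-gate opens on hyperpolarization, and an analogous
#' depolarization-activated gate `n` for the potassium conductance.
#' Integration uses fixed-step 4th-order Runge-Kutta.
#'
#' A constant holding current is computed so that the pre-stimulus
#' membrane potential sits at `protocol$holding_target` (the protocol's
#' steady state), and the step current is added between `onset` and
#' `onset + duration`.
#'
#' @param params a [neuron_params()] object.
#' @param protocol a [step_protocol()] with `step_amp` in pA.
#' @param seed optional integer seed for the observation noise.
#' @param dt integration step in ms (must be <= 0.05).
#' @param post_ms recording time after step offset, ms (default 300,
#'   covering the rebound window).
#' @return An [ephys_trace()] (unit mV) with the ground-truth parameters
#'   attached in `meta$params`.
#' @export
simulate_neuron <- function(params, protocol = step_protocol(),
                            seed = NULL, dt = 0.05, post_ms = 300) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "step_protocol"))
  if (dt > 0.05 + 1e-12) stop("integration step must be <= 0.05 ms")

  p <- params
  m_inf <- function(V) 1 / (1 + exp((V - p$V_half_h) / p$k_h))
  n_inf <- function(V) 1 / (1 + exp(-(V - p$V_half_K) / p$k_K))

  V0 <- protocol$holding_target
  # holding current balancing the membrane at V0 with gates at steady state
  i_hold <- p$g_L * (V0 - p$E_L) +
    p$g_h * m_inf(V0) * (V0 - p$E_h) +
    p$g_K * n_inf(V0) * (V0 - p$E_K_rev)

  t_total <- protocol$onset + protocol$duration + post_ms
  n_samp <- floor(t_total / dt) + 1L
  times <- (seq_len(n_samp) - 1) * dt
  i_inj <- i_hold + ifelse(times >= protocol$onset &
                             times < protocol$onset + protocol$duration,
                           protocol$step_amp, 0)

  deriv <- function(s, I) {
    V <- s[1L]; m <- s[2L]; n <- s[3L]
    c((-p$g_L * (V - p$E_L) - p$g_h * m * (V - p$E_h) -
         p$g_K * n * (V - p$E_K_rev) + I) / p$C_m,
      (m_inf(V) - m) / p$tau_h,
      (n_inf(V) - n) / p$tau_K)
  }

  out <- numeric(n_samp)
  s <- c(V0, m_inf(V0), n_inf(V0))
  out[1L] <- s[1L]
  for (i in seq_len(n_samp - 1L)) {
    # injected current is piecewise constant over each integration interval
    I1 <- i_inj[i]
    k1 <- deriv(s, I1)
    k2 <- deriv(s + dt / 2 * k1, I1)
    k3 <- deriv(s + dt / 2 * k2, I1)
    k4 <- deriv(s + dt * k3, I1)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(s)))
      stop(sprintf("integration failure: non-finite state at step %d (t = %.3f ms)",
                   i, times[i + 1L]))
    out[i + 1L] <- s[1L]
  }

  if (p$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + stats::rnorm(n_samp, 0, p$noise_sd)
  }

  ephys_trace(out, dt = dt, unit = "mV", protocol = protocol,
              junction_corrected = TRUE,
              meta = list(params = unclass(p), seed = seed,
                          holding_current_pA = i_hold))
}
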