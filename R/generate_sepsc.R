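#' Biexponential synaptic-current kernel
#'
#' Difference-of-exponentials kernel
#' \eqn{a (e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}})} scaled so its
#' extremum equals `amp`.
#'
#' @param t time vector, ms (values before 0 give 0).
#' @param amp peak amplitude, pA (sign preserved).
#' @param tau_rise,tau_decay time constants, ms.
#' @return numeric vector of kernel values.
#' @export
biexp_kernel <- function(t, amp, tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak_raw <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  amp / peak_raw * out
}

#' Generate a synthetic gap-free sEPSC recording
#'
#' Draws homogeneous Poisson event times over the recording, superposes
#' one biexponential kernel per event (peak = `preset$amp`), and adds
#' Gaussian baseline noise. The ground-truth event times are returned so
#' detection performance can be scored.
#'
#' @param preset an [sepsc_preset()].
#' @param seed integer seed (the generator is bit-reproducible given the
#'   seed).
#' @param dt sampling interval, ms (default 0.1, i.e. 10 kHz).
#' @return A list with elements `trace` (an [ephys_trace()], unit pA,
#'   gap-free) and `ground_truth` (sorted event times in ms).
#' @export
generate_sepsc_trace <- function(preset, seed = NULL, dt = 0.1) {
  stopifnot(inherits(preset, "sepsc_preset"))
  if (preset$rate * preset$duration > 1e6)
    stop("rate * duration exceeds 1e6 events; refusing runaway generation")
  if (!is.null(seed)) set.seed(seed)

  dur_ms <- preset$duration * 1000
  n_samp <- floor(dur_ms / dt)
  n_ev <- stats::rpois(1L, preset$rate * preset$duration)
  ev_times <- sort(stats::runif(n_ev, 0, dur_ms))

  y <- numeric(n_samp)
  if (n_ev > 0) {
    klen <- ceiling(10 * preset$tau_decay / dt)
    kern <- biexp_kernel((0:klen) * dt, preset$amp,
                         preset$tau_rise, preset$tau_decay)
    for (tv in ev_times) {
      i0 <- floor(tv / dt) + 1L
      idx <- i0:min(n_samp, i0 + klen)
      y[idx] <- y[idx] + kern[seq_along(idx)]
    }
  }
  if (preset$noise_sd > 0)
    y <- y + stats::rnorm(n_samp, 0, preset$noise_sd)

  trace <- ephys_trace(y, dt = dt, unit = "pA", protocol = NULL,
                       meta = list(preset = unclass(preset), seed = seed,
                                   ground_truth_ms = ev_times))
  list(trace = trace, ground_truth = ev_times)
}
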