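#' Passive properties, sag and rebound from a hyperpolarizing step
#'
#' Quantifies the membrane response to a hyperpolarizing current step.
#' With baseline voltage `V0` (mean over the 50 ms preceding the onset):
#' the minimum deflection `C = min(V) - V0` within the step, the
#' steady-state deflection `A` (mean deflection over the last 20% of the
#' step), and a single-exponential fit
#' `defl(t) = B (1 - exp(-(t - onset)/tau_m))` restricted to the initial
#' falling phase where the deflection lies between `0.10 C` and `0.90 C`,
#' giving the extrapolated asymptote `B` and membrane time constant
#' `tau_m`. From these:
#' \itemize{
#'   \item `R_in = A / step_amp`, reported in MOhm;
#'   \item `sag_sub = 100 (C - A)/C` (percent, from raw extrema);
#'   \item `sag_fit = 100 (B - A)/B` (percent, from the fitted asymptote);
#'   \item `rebound`: maximum voltage above baseline in the 200 ms after
#'     step offset, mV.
#' }
#'
#' @param trace a voltage [ephys_trace()].
#' @param protocol a [step_protocol()]; if `NULL` the trace's own
#'   protocol is used. `step_amp` must be negative (hyperpolarizing) and
#'   nonzero.
#' @param baseline_ms baseline window before onset, ms (default 50).
#' @param steady_frac final fraction of the step used for the
#'   steady-state deflection (default 0.2).
#' @param rebound_ms post-offset window for the rebound, ms (default 200).
#' @return An object of class `passive_fit`: a list with `V0`, `A`, `B`,
#'   `C`, `tau_m`, `R_in`, `sag_sub`, `sag_fit`, `rebound` and
#'   `fit_converged`. When the exponential fit fails, `B`, `tau_m` and
#'   `sag_fit` are `NA` and `fit_converged` is `FALSE`.
#' @export
fit_passive_response <- function(trace, protocol = NULL, baseline_ms = 50,
                                 steady_frac = 0.2, rebound_ms = 200) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$unit != "mV") stop("passive fit needs a voltage trace")
  if (is.null(protocol)) protocol <- trace$protocol
  if (is.null(protocol)) stop("no step protocol available")
  if (protocol$step_amp == 0) stop("step_amp must be nonzero")
  if (protocol$step_amp > 0)
    stop("passive fit expects a hyperpolarizing (negative) current step")
  tt <- trace_time(trace)
  v <- trace$samples
  on <- protocol$onset; off <- on + protocol$duration
  if (on < baseline_ms)
    stop("need at least ", baseline_ms, " ms of baseline before the step onset")

  V0 <- mean(v[tt >= on - baseline_ms & tt < on])
  in_step <- tt > on & tt <= off
  defl <- v[in_step] - V0
  ts <- tt[in_step] - on

  i_min <- which.min(defl)
  C <- defl[i_min]
  A <- mean(defl[ts >= (1 - steady_frac) * protocol$duration])

  # falling phase up to the minimum, deflection within [0.10 C, 0.90 C]
  fall <- seq_len(i_min)
  band <- fall[defl[fall] / C >= 0.10 & defl[fall] / C <= 0.90]
  B <- NA_real_; tau_m <- NA_real_; converged <- FALSE
  if (length(band) >= 5L) {
    df <- data.frame(t = ts[band], y = defl[band])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ B * (1 - exp(-t / tau)), data = df,
                        start = list(B = C, tau = max(ts[band][length(band)] / 2,
                                                      1)),
                        lower = c(B = -Inf, tau = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      B <- unname(cf["B"]); tau_m <- unname(cf["tau"])
      converged <- TRUE
    }
  }

  r_in <- (A / protocol$step_amp) * 1000  # mV/pA = GOhm -> MOhm
  sag_sub <- if (C != 0) 100 * (C - A) / C else 0
  sag_fit <- if (converged && B != 0) 100 * (B - A) / B else NA_real_
  post <- tt > off & tt <= off + rebound_ms
  rebound <- if (any(post)) max(v[post]) - V0 else NA_real_

  structure(list(V0 = V0, A = A, B = B, C = C, tau_m = tau_m, R_in = r_in,
                 sag_sub = sag_sub, sag_fit = sag_fit, rebound = rebound,
                 fit_converged = converged),
            class = "passive_fit")
}

#' @export
print.passive_fit <- function(x, ...) {
  cat(sprintf("<passive_fit> V0=%.1f mV, A=%.2f, B=%.2f, C=%.2f mV, tau_m=%.1f ms\n",
              x$V0, x$A, x$B, x$C, x$tau_m))
  cat(sprintf("  R_in=%.0f MOhm, sag_sub=%.1f%%, sag_fit=%.1f%%, rebound=%.2f mV\n",
              x$R_in, x$sag_sub, x$sag_fit, x$rebound))
  invisible(x)
}

#' Leak-subtracted I-V analysis with Boltzmann activation fit
#'
#' Analyzes a family of voltage-clamp current traces evoked by a series
#' of voltage steps (by default 12 steps of 10 mV from a -90 mV
#' holding). The steady-state current of each step is taken over its
#' last 20%; an ohmic leak is fitted to the two most hyperpolarized
#' steps and subtracted everywhere; currents are normalized to membrane
#' capacitance (specific current, pA/pF); the specific conductance is
#' the specific current divided by a fixed 100 mV electrochemical force
#' for potassium (or by `V - E_K` when `driving = "physical"`); and a
#' Boltzmann sigmoid
#' `G(V) = G_max / (1 + exp(-(V - V_half)/slope_k))` is fitted per cell.
#'
#' @param traces list of current [ephys_trace()] objects, or a numeric
#'   vector of steady-state currents (pA), one per step.
#' @param protocol a [step_protocol()] describing the voltage-step
#'   family (`step_amp` = first step potential in mV, `step_increment`,
#'   `n_steps`).
#' @param C_m_est membrane capacitance estimate, pF.
#' @param driving `"fixed"` (100 mV, the default) or `"physical"`
#'   (`V - E_K`).
#' @param E_K potassium reversal used by the `"physical"` variant, mV.
#' @param steady_frac final fraction of each step averaged for the
#'   steady-state current.
#' @return An object of class `iv_result` with `step_voltages`,
#'   `leak_params` (conductance nS, reversal mV), `specific_currents`,
#'   `G`, `G_max`, `V_half`, `slope_k` and `flagged` (TRUE when the fit
#'   was rejected: non-convergence or non-positive `G_max`).
#' @export
analyze_iv <- function(traces, protocol, C_m_est, driving = c("fixed", "physical"),
                       E_K = -100, steady_frac = 0.2) {
  driving <- match.arg(driving)
  stopifnot(inherits(protocol, "step_protocol"))
  if (C_m_est <= 0) stop("C_m_est must be > 0")

  if (is.list(traces)) {
    iss <- vapply(traces, function(tr) {
      stopifnot(inherits(tr, "ephys_trace"))
      tt <- trace_time(tr)
      on <- protocol$onset; off <- on + protocol$duration
      mean(tr$samples[tt >= off - steady_frac * protocol$duration & tt <= off])
    }, numeric(1L))
  } else {
    iss <- as.numeric(traces)
  }
  n <- length(iss)
  if (n < 4L) stop("need at least 4 usable voltage steps")
  volts <- protocol$step_amp + (seq_len(n) - 1L) * protocol$step_increment

  # ohmic leak from the two most hyperpolarized steps
  ord <- order(volts)[1:2]
  g_leak <- (iss[ord[2L]] - iss[ord[1L]]) / (volts[ord[2L]] - volts[ord[1L]])
  e_leak <- if (g_leak != 0) volts[ord[1L]] - iss[ord[1L]] / g_leak else NA_real_
  leak <- if (g_leak != 0) g_leak * (volts - e_leak) else rep(0, n)
  i_sub <- iss - leak

  i_spec <- i_sub / C_m_est
  denom <- if (driving == "fixed") 100 else (volts - E_K)
  G <- i_spec / denom

  flagged <- FALSE
  G_max <- NA_real_; V_half <- NA_real_; slope_k <- NA_real_
  if (max(abs(G)) < 1e-9) {
    flagged <- TRUE
  } else {
    df <- data.frame(v = volts, g = G)
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ gmax / (1 + exp(-(v - vh) / k)), data = df,
                        start = list(gmax = max(G), vh = stats::median(volts),
                                     k = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      flagged <- TRUE
    } else {
      cf <- stats::coef(fit)
      G_max <- unname(cf["gmax"]); V_half <- unname(cf["vh"])
      slope_k <- unname(cf["k"])
      if (!is.finite(G_max) || G_max <= 0) flagged <- TRUE
    }
  }

  structure(list(step_voltages = volts,
                 leak_params = c(conductance_nS = g_leak, reversal_mV = e_leak),
                 specific_currents = i_spec, G = G, G_max = G_max,
                 V_half = V_half, slope_k = slope_k, driving = driving,
                 flagged = flagged),
            class = "iv_result")
}

#' @export
print.iv_result <- function(x, ...) {
  cat(sprintf("<iv_result> %d steps %g..%g mV; G_max=%.3g nS/pF, V_half=%.1f mV, k=%.2f mV%s\n",
              length(x$step_voltages), min(x$step_voltages),
              max(x$step_voltages), x$G_max, x$V_half, x$slope_k,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Action-potential waveform statistics
#'
#' From a current-clamp trace containing evoked spikes during a square
#' depolarizing step: the threshold is the voltage at the first crossing
#' of `dV/dt >= dvdt_thresh` (default 20 mV/ms), the peak is the maximum
#' voltage, `max_rise` the maximum `dV/dt`, and the width the time spent
#' above the half level `(threshold + peak)/2`.
#'
#' @param trace a voltage [ephys_trace()].
#' @param protocol a [step_protocol()]; defaults to the trace's own.
#' @param dvdt_thresh threshold-detection slope criterion, mV/ms.
#' @return An object of class `ap_stats` with `peak`, `threshold`,
#'   `max_rise`, `width` and `n_spikes`; all-`NA` (with `n_spikes = 0`)
#'   when no spike is present.
#' @export
analyze_ap <- function(trace, protocol = NULL, dvdt_thresh = 20) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$unit != "mV") stop("AP analysis needs a voltage trace")
  if (is.null(protocol)) protocol <- trace$protocol
  tt <- trace_time(trace)
  v <- trace$samples
  if (!is.null(protocol)) {
    keep <- tt >= protocol$onset & tt <= protocol$onset + protocol$duration
    tt <- tt[keep]; v <- v[keep]
  }
  dvdt <- c(NA_real_, diff(v) / trace$dt)
  cross <- which(dvdt >= dvdt_thresh)
  empty <- structure(list(peak = NA_real_, threshold = NA_real_,
                          max_rise = NA_real_, width = NA_real_,
                          n_spikes = 0L), class = "ap_stats")
  if (length(cross) == 0) return(empty)

  threshold <- v[cross[1L]]
  peak <- max(v)
  if (peak <= threshold) return(empty)
  max_rise <- max(dvdt, na.rm = TRUE)
  half <- (threshold + peak) / 2
  above <- v >= half
  width <- sum(above) * trace$dt
  # count spikes as upward half-level crossings
  n_spikes <- sum(diff(above) == 1L) + as.integer(above[1L])

  structure(list(peak = peak, threshold = threshold, max_rise = max_rise,
                 width = width, n_spikes = n_spikes),
            class = "ap_stats")
}

#' @export
print.ap_stats <- function(x, ...) {
  if (x$n_spikes == 0L) {
    cat("<ap_stats> no spike detected\n")
  } else {
    cat(sprintf("<ap_stats> %d spike(s): peak %.1f mV, threshold %.1f mV, max dV/dt %.0f mV/ms, width %.2f ms\n",
                x$n_spikes, x$peak, x$threshold, x$max_rise, x$width))
  }
  invisible(x)
}
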