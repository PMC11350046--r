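#' Build a detection template
#'
#' A biexponential kernel sampled at the trace sampling interval,
#' normalized to unit (negative, inward) peak, used by
#' [detect_events()].
#'
#' @param dt sampling interval, ms.
#' @param tau_rise,tau_decay kernel time constants, ms (defaults match
#'   the WT event kinetics).
#' @param length_ms template length, ms.
#' @return An object of class `sepsc_template`.
#' @export
sepsc_template <- function(dt, tau_rise = 0.8, tau_decay = 4,
                           length_ms = 25) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  t <- seq(0, length_ms, by = dt)
  w <- biexp_kernel(t, amp = -1, tau_rise = tau_rise, tau_decay = tau_decay)
  structure(list(samples = w, dt = dt, tau_rise = tau_rise,
                 tau_decay = tau_decay, length_ms = length_ms),
            class = "sepsc_template")
}

#' Detect synaptic events by sliding template matching
#'
#' Slides the template along the trace; at every offset the template is
#' optimally scaled and offset onto the data by least squares, and the
#' detection criterion is the fitted scale divided by the standard error
#' of the fit (a Clements-Bekkers style criterion). Events are declared
#' at local maxima of the criterion above `threshold`, separated by at
#' least `refractory` ms, and are kept only when the fitted amplitude
#' exceeds `amp_sd_mult` times a robust (MAD-based) estimate of the
#' baseline noise SD -- a deterministic stand-in for a manual
#' false-positive check.
#'
#' @param trace a gap-free current [ephys_trace()].
#' @param template an [sepsc_template()] at the trace `dt`; built from
#'   the defaults when `NULL`.
#' @param threshold detection criterion threshold (default 4).
#' @param refractory minimum event separation, ms (default 5).
#' @param amp_sd_mult amplitude filter in units of robust noise SD
#'   (default 3).
#' @return An object of class `event_list`: a data.frame with columns
#'   `time_ms` (template onset), `scale_pA` (fitted, negative = inward)
#'   and `criterion`, sorted by time, with the noise SD estimate in
#'   `attr(, "noise_sd")`.
#' @export
detect_events <- function(trace, template = NULL, threshold = 4,
                          refractory = 5, amp_sd_mult = 3) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$unit != "pA") stop("event detection needs a current trace")
  if (is.null(template)) template <- sepsc_template(dt = trace$dt)
  stopifnot(inherits(template, "sepsc_template"))
  if (abs(template$dt - trace$dt) > 1e-9)
    stop("template must be sampled at the trace dt")
  y <- trace$samples
  w <- template$samples
  L <- length(w)
  n <- length(y)
  if (L >= n) stop("template longer than trace")

  # running sums over windows of length L via one-sided moving filters
  ones <- rep(1, L)
  run <- function(x, coefs) {
    r <- stats::filter(x, coefs, method = "convolution", sides = 1)
    as.numeric(r[L:n])  # value at i corresponds to window starting at i-L+1
  }
  Sy  <- run(y, ones)
  Syy <- run(y^2, ones)
  Swy <- run(y, rev(w))      # sum_j w_j y_(i+j-1) for window start i
  Sw  <- sum(w); Sww <- sum(w^2)
  den <- Sww - Sw^2 / L
  scale <- (Swy - Sw * Sy / L) / den
  sse <- pmax(Syy - Sy^2 / L - scale^2 * den, 0)
  se <- sqrt(sse / (L - 1))
  # a perfect (noiseless) fit has zero residual: infinite criterion
  crit <- ifelse(se > 0, abs(scale) / se,
                 ifelse(abs(scale) > 0, Inf, 0))
  # the template is unit-negative: inward events fit with positive scale
  crit[scale < 0] <- 0

  noise_sd <- stats::mad(diff(y)) / sqrt(2)

  # one candidate per contiguous above-threshold region: its criterion peak
  above <- crit >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cand <- vapply(which(r$values), function(j) {
    span <- starts[j]:ends[j]
    span[which.max(crit[span])]
  }, integer(1L))
  # greedy non-maximum suppression within the refractory window
  keep <- logical(length(cand))
  if (length(cand) > 0) {
    ord <- cand[order(crit[cand], decreasing = TRUE)]
    ref_n <- ceiling(refractory / trace$dt)
    taken <- integer(0)
    for (i in ord) {
      if (length(taken) == 0 || min(abs(taken - i)) >= ref_n)
        taken <- c(taken, i)
    }
    cand <- sort(taken)
  }
  amp_ok <- abs(scale[cand]) >= amp_sd_mult * noise_sd
  cand <- cand[amp_ok]
  # deterministic stand-in for the manual false-positive check: drop
  # low-amplitude shoulders riding the decay of a larger event within one
  # template length
  if (length(cand) > 1L) {
    span_n <- L
    keep <- rep(TRUE, length(cand))
    for (j in 2:length(cand)) {
      prev <- which(keep[seq_len(j - 1L)])
      if (length(prev) == 0) next
      jp <- max(prev)
      if (cand[j] - cand[jp] < span_n &&
          abs(scale[cand[j]]) < 0.7 * abs(scale[cand[jp]]))
        keep[j] <- FALSE
    }
    cand <- cand[keep]
  }

  ev <- data.frame(time_ms = (cand - 1) * trace$dt,
                   scale_pA = -scale[cand],  # template peak is -1: pA, inward
                   criterion = crit[cand])
  attr(ev, "noise_sd") <- noise_sd
  attr(ev, "duration_s") <- n * trace$dt / 1000
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Average detected events into a mean waveform
#'
#' Snippets are aligned on the detection time (the template-onset
#' position, whose jitter is small because the detection criterion is a
#' whole-template fit), a window is extracted around it (30% before,
#' 70% after), the per-snippet baseline -- the mean over the part of
#' the pre-detection window that safely precedes the rising phase
#' (more than `baseline_gap_ms` before the alignment point) -- is
#' subtracted, and the snippets are averaged pointwise. Events whose
#' window extends past either end of the trace are dropped.
#'
#' @param trace the current [ephys_trace()] the events came from.
#' @param events an `event_list` from [detect_events()].
#' @param window_ms snippet window length, ms (default 50).
#' @param baseline_gap_ms pre-alignment interval excluded from the
#'   baseline, ms.
#' @return A list with `t_ms` (time relative to the detection point),
#'   `mean` (averaged baseline-subtracted waveform, pA) and `n_events`,
#'   or `NULL` when no event is usable.
#' @export
average_events <- function(trace, events, window_ms = 50,
                           baseline_gap_ms = 10) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (NROW(events) == 0) return(NULL)
  dt <- trace$dt
  pre_n <- round(0.3 * window_ms / dt)
  post_n <- round(0.7 * window_ms / dt)
  n <- length(trace$samples)
  idx0 <- round(events$time_ms / dt) + 1L
  ok <- idx0 - pre_n >= 1L & idx0 + post_n <= n
  idx0 <- idx0[ok]
  if (length(idx0) == 0) return(NULL)
  rel <- -pre_n:post_n
  base_sel <- rel < -round(baseline_gap_ms / dt)
  if (!any(base_sel)) base_sel <- rel < 0
  grab <- function(centers) {
    vapply(centers, function(i) {
      s <- trace$samples[i + rel]
      s - mean(s[base_sel])
    }, numeric(length(rel)))
  }
  first <- rowMeans(grab(idx0))
  # second pass: realign each snippet on the first-pass mean by
  # cross-correlation, removing residual template-mismatch jitter
  max_shift <- round(2 / dt)
  shifts <- -max_shift:max_shift
  idx1 <- vapply(seq_along(idx0), function(j) {
    i <- idx0[j]
    cc <- vapply(shifts, function(s) {
      lo <- i + s - pre_n; hi <- i + s + post_n
      if (lo < 1L || hi > n) return(-Inf)
      sum(trace$samples[lo:hi] * first)
    }, numeric(1L))
    as.integer(i + shifts[which.max(cc)])
  }, integer(1L))
  ok2 <- idx1 - pre_n >= 1L & idx1 + post_n <= n
  idx1 <- idx1[ok2]
  list(t_ms = rel * dt, mean = rowMeans(grab(idx1)), n_events = length(idx1))
}

#' Frequency and kinetic summary of detected events
#'
#' Frequency is the event count divided by the recording duration.
#' Amplitude, half-width and rate of rise are read off the averaged
#' waveform: the amplitude is the absolute extremum relative to the
#' pre-event baseline, the half-width is the time spent beyond half
#' amplitude (linear interpolation at the crossings), and the rate of
#' rise is the maximum absolute slope between event onset and peak.
#'
#' @param avg mean waveform from [average_events()] (may be `NULL`).
#' @param events an `event_list` from [detect_events()].
#' @param duration_s recording duration in s; taken from the event list
#'   attribute when missing.
#' @return An object of class `waveform_stats`: `frequency` (Hz),
#'   `amplitude` (pA, absolute), `half_width` (ms), `rate_of_rise`
#'   (pA/ms) and `n_events`.
#' @export
waveform_stats <- function(avg, events, duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- attr(events, "duration_s")
  if (is.null(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive")
  n_ev <- NROW(events)
  freq <- n_ev / duration_s
  if (is.null(avg) || n_ev == 0) {
    return(structure(list(frequency = freq, amplitude = NA_real_,
                          half_width = NA_real_, rate_of_rise = NA_real_,
                          n_events = n_ev), class = "waveform_stats"))
  }
  y <- avg$mean
  dt <- avg$t_ms[2L] - avg$t_ms[1L]
  # baseline from the pre-peak region that precedes the rising phase
  base_sel <- avg$t_ms < -10
  if (!any(base_sel)) base_sel <- avg$t_ms < 0
  base <- mean(y[base_sel])
  d <- y - base
  i_pk <- which.max(abs(d))
  amp <- abs(d[i_pk])
  half <- amp / 2
  a <- abs(d)

  # half-width: interpolated time beyond half amplitude around the peak
  i_lo <- i_pk
  while (i_lo > 1L && a[i_lo - 1L] >= half) i_lo <- i_lo - 1L
  i_hi <- i_pk
  while (i_hi < length(a) && a[i_hi + 1L] >= half) i_hi <- i_hi + 1L
  t_lo <- avg$t_ms[i_lo]
  if (i_lo > 1L)
    t_lo <- t_lo - dt * (a[i_lo] - half) / (a[i_lo] - a[i_lo - 1L])
  t_hi <- avg$t_ms[i_hi]
  if (i_hi < length(a))
    t_hi <- t_hi + dt * (a[i_hi] - half) / (a[i_hi] - a[i_hi + 1L])
  hw <- t_hi - t_lo

  # rate of rise on the rising phase (last sub-5%-amplitude point to the
  # peak), as the steepest centered secant over a 0.4 ms span -- less
  # noise-sensitive than a single-sample difference
  onset_cand <- which(a[seq_len(i_pk)] <= 0.05 * amp)
  i_on <- if (length(onset_cand) > 0) max(onset_cand) else 1L
  k <- max(1L, round(0.2 / dt))
  ror <- if (i_pk > i_on) {
    ctr <- i_on:i_pk
    lo <- pmax(ctr - k, 1L); hi <- pmin(ctr + k, length(d))
    max(abs(d[hi] - d[lo]) / ((hi - lo) * dt))
  } else NA_real_

  structure(list(frequency = freq, amplitude = amp, half_width = hw,
                 rate_of_rise = ror, n_events = n_ev),
            class = "waveform_stats")
}

#' @export
print.waveform_stats <- function(x, ...) {
  cat(sprintf("<waveform_stats> %d events: %.3g Hz, %.3g pA, half-width %.3g ms, rate of rise %.3g pA/ms\n",
              x$n_events, x$frequency, x$amplitude, x$half_width,
              x$rate_of_rise))
  invisible(x)
}

#' One-call sEPSC analysis of a trace
#'
#' Runs [detect_events()], [average_events()] and [waveform_stats()]
#' with shared defaults.
#'
#' @inheritParams detect_events
#' @inheritParams average_events
#' @return A list `list(events, avg, stats)`.
#' @export
analyze_sepsc_trace <- function(trace, template = NULL, threshold = 4,
                                refractory = 5, window_ms = 50) {
  ev <- detect_events(trace, template, threshold = threshold,
                      refractory = refractory)
  avg <- average_events(trace, ev, window_ms = window_ms)
  st <- waveform_stats(avg, ev)
  list(events = ev, avg = avg, stats = st)
}
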