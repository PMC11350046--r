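#' Construct an electrophysiology trace
#'
#' A uniformly sampled time series holding either a membrane-voltage
#' recording (current clamp, mV) or a membrane-current recording
#' (voltage clamp, pA), plus the stimulation protocol it was acquired
#' under and optional generator metadata.
#'
#' @param samples numeric vector of sample values (mV or pA).
#' @param dt sampling interval in ms; must be positive.
#' @param unit `"mV"` or `"pA"`.
#' @param protocol a [step_protocol()] object, or `NULL` for gap-free
#'   recordings.
#' @param junction_corrected logical; has the liquid junction potential
#'   already been subtracted?
#' @param meta optional named list of metadata (generator parameters,
#'   seed, ground-truth event times, ...).
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(samples, dt, unit = c("mV", "pA"), protocol = NULL,
                        junction_corrected = FALSE, meta = list()) {
  unit <- match.arg(unit)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ms)")
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples")
  if (!is.null(protocol) && !inherits(protocol, "step_protocol"))
    stop("'protocol' must be a step_protocol or NULL")
  structure(
    list(samples = samples, dt = dt, unit = unit, protocol = protocol,
         junction_corrected = isTRUE(junction_corrected), meta = meta),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  dur <- length(x$samples) * x$dt
  cat(sprintf("<ephys_trace> %d samples @ dt=%.3g ms (%.3g s), unit %s%s\n",
              length(x$samples), x$dt, dur / 1000, x$unit,
              if (x$junction_corrected) ", junction-corrected" else ""))
  if (!is.null(x$protocol))
    cat(sprintf("  step: %+g %s at %g ms for %g ms (holding %g mV)\n",
                x$protocol$step_amp, if (x$unit == "mV") "pA" else "mV",
                x$protocol$onset, x$protocol$duration,
                x$protocol$holding_target))
  invisible(x)
}

#' Time axis of a trace
#'
#' @param trace an [ephys_trace()].
#' @return numeric vector of sample times in ms, starting at 0.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "ephys_trace"))
  (seq_along(trace$samples) - 1) * trace$dt
}

#' Construct a step stimulation protocol
#'
#' Describes a square current (current clamp) or voltage (voltage clamp)
#' step: the pre-stimulus holding target, step amplitude, onset and
#' duration, and -- for step families -- the number of steps and the
#' per-step increment.
#'
#' @param holding_target pre-stimulus membrane potential in mV.
#' @param step_amp step amplitude (pA for current steps, mV for voltage
#'   steps).
#' @param onset step onset in ms from the start of the sweep.
#' @param duration step duration in ms; must be positive.
#' @param n_steps number of steps in a family (1 for a single step).
#' @param step_increment increment between successive steps (mV or pA).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding_target = -80, step_amp = -100,
                          onset = 100, duration = 500,
                          n_steps = 1L, step_increment = 0) {
  if (duration <= 0) stop("'duration' must be positive")
  if (onset < 0) stop("'onset' must be >= 0")
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  structure(
    list(holding_target = holding_target, step_amp = step_amp,
         onset = onset, duration = duration,
         n_steps = as.integer(n_steps), step_increment = step_increment),
    class = "step_protocol"
  )
}

#' Subtract the liquid junction potential from a voltage trace
#'
#' The offset between pipette and bath solutions shifts all recorded
#' voltages; it is corrected arithmetically by subtracting `vj` from
#' every sample. Correcting a trace twice is refused.
#'
#' @param trace a voltage [ephys_trace()].
#' @param vj junction potential in mV (default 15).
#' @return The corrected trace with `junction_corrected = TRUE`.
#' @export
correct_junction_potential <- function(trace, vj = 15) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$unit != "mV")
    stop("junction potential correction applies to voltage traces only")
  if (trace$junction_corrected)
    stop("trace is already junction-corrected; refusing to correct twice")
  trace$samples <- trace$samples - vj
  trace$junction_corrected <- TRUE
  trace
}
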