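#' Single recorded or simulated sweep
#'
#' A sweep holds synchronously sampled channels from one protocol epoch:
#' membrane voltage (mV), membrane/command current (pA) and the stimulus
#' waveform. At least one of `voltage`/`current` must be present and all
#' channels must have equal length.
#'
#' @param t0 Start time of the sweep (s).
#' @param dt Sampling interval (s/sample); recordings here are typically
#'   50 kHz (`dt = 2e-5`) but any positive `dt` is accepted.
#' @param voltage Optional numeric vector, membrane potential (mV).
#' @param current Optional numeric vector, membrane current (pA).
#' @param stimulus Optional numeric vector, injected current (pA) or
#'   command voltage (mV) depending on clamp mode.
#' @param condition Pharmacological condition, one of `"control"`,
#'   `"TEA"`, `"DTX"`.
#' @param ljp_corrected Logical; `TRUE` once the liquid junction
#'   potential has been subtracted from the voltage channel.
#' @return An object of class `"sweep_trace"`.
#' @export
sweep_trace <- function(t0 = 0, dt, voltage = NULL, current = NULL,
                        stimulus = NULL, condition = "control",
                        ljp_corrected = FALSE) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  if (is.null(voltage) && is.null(current))
    stop("at least one of 'voltage'/'current' must be present")
  condition <- match.arg(condition, c("control", "TEA", "DTX"))
  lens <- vapply(Filter(Negate(is.null),
                        list(voltage, current, stimulus)), length, 1L)
  if (length(unique(lens)) > 1L)
    stop("channel length mismatch: ", paste(lens, collapse = ", "))
  structure(list(t0 = t0, dt = dt, voltage = voltage, current = current,
                 stimulus = stimulus, condition = condition,
                 ljp_corrected = isTRUE(ljp_corrected)),
            class = "sweep_trace")
}

#' @export
print.sweep_trace <- function(x, ...) {
  n <- length(if (!is.null(x$voltage)) x$voltage else x$current)
  cat(sprintf("<sweep_trace> %d samples @ %.4g kHz, %.3g s, %s%s\n",
              n, 1e-3 / x$dt, n * x$dt, x$condition,
              if (x$ljp_corrected) ", LJP-corrected" else ""))
  invisible(x)
}

sweep_times <- function(sw) {
  n <- length(if (!is.null(sw$voltage)) sw$voltage else sw$current)
  sw$t0 + sw$dt * (seq_len(n) - 1L)
}

#' Stimulation protocol descriptor
#'
#' Describes the stimulus structure shared by the sweeps of a
#' [sweep_set()]. Constructors exist per protocol kind; fields not
#' applicable to a kind are absent.
#'
#' @param step_amplitude Step amplitude(s), pA; a vector gives one
#'   amplitude per sweep (the usual incrementing family).
#' @param step_onset,step_offset Step timing (s).
#' @param holding Holding potential (mV).
#' @name protocols
#' @return An object of class `"protocol"`.
#' @export
protocol_long_step <- function(step_amplitude, step_onset = 0.2,
                               step_offset = 1.2, holding = -70) {
  stopifnot(step_onset < step_offset, is.numeric(step_amplitude))
  structure(list(kind = "long_step", step_amplitude = step_amplitude,
                 step_onset = step_onset, step_offset = step_offset,
                 holding = holding), class = "protocol")
}

#' @rdname protocols
#' @param pulse_width Pulse width (ms).
#' @param pulse_rate Pulse rate (Hz).
#' @param n_pulses Number of pulses in the train.
#' @param onset Time of first pulse (s).
#' @export
protocol_pulse_train <- function(step_amplitude, pulse_rate,
                                 pulse_width = 10, n_pulses = 20,
                                 onset = 0.1, holding = -70) {
  stopifnot(pulse_rate > 0, pulse_width > 0, n_pulses >= 1)
  structure(list(kind = "pulse_train", step_amplitude = step_amplitude,
                 pulse_width = pulse_width, pulse_rate = pulse_rate,
                 n_pulses = n_pulses, onset = onset, holding = holding),
            class = "protocol")
}

#' @rdname protocols
#' @param step_voltages Test step voltages (mV), strictly increasing.
#' @param prestep_voltage,prestep_duration Inactivating prestep (mV, s);
#'   the 2-s step to -36 mV used to isolate non-inactivating current.
#' @param step_duration Test step duration (s).
#' @param post_voltage Voltage after the step, where tails are measured.
#' @export
protocol_vstep_family <- function(step_voltages = seq(-56, 24, by = 10),
                                  prestep_voltage = -36,
                                  prestep_duration = 2,
                                  step_duration = 0.25,
                                  holding = -56, post_voltage = -56,
                                  step_onset = 0.02) {
  stopifnot(all(diff(step_voltages) > 0))
  structure(list(kind = "vstep_family", step_voltages = step_voltages,
                 prestep_voltage = prestep_voltage,
                 prestep_duration = prestep_duration,
                 step_duration = step_duration, holding = holding,
                 post_voltage = post_voltage, step_onset = step_onset),
            class = "protocol")
}

#' @rdname protocols
#' @param stim_times Stimulus times (s).
#' @param duration Sweep duration (s).
#' @param kind `"evoked_psc"` (paired pulse) or `"train_psc"`.
#' @export
protocol_psc <- function(stim_times, holding = 0, duration = NULL,
                         kind = c("evoked_psc", "train_psc")) {
  kind <- match.arg(kind)
  stopifnot(length(stim_times) >= 1, all(stim_times >= 0))
  if (is.null(duration)) duration <- max(stim_times) + 0.3
  if (any(stim_times >= duration)) stop("stim_times outside sweep")
  structure(list(kind = kind, stim_times = stim_times, holding = holding,
                 duration = duration), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$kind, "\n")
  invisible(x)
}

#' Ordered collection of sweeps sharing one protocol
#'
#' @param sweeps List of [sweep_trace()] objects sharing `dt`.
#' @param protocol A [protocols] object.
#' @param cell_id Character cell identifier.
#' @param metadata Free-form list; generators store ground truth here
#'   (spike times, component currents, ...).
#' @return An object of class `"sweep_set"`.
#' @export
sweep_set <- function(sweeps, protocol, cell_id = "cell", metadata = list()) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1,
            inherits(protocol, "protocol"))
  if (!all(vapply(sweeps, inherits, TRUE, "sweep_trace")))
    stop("all elements of 'sweeps' must be sweep_trace objects")
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-12) stop("sweeps must share dt")
  structure(list(cell_id = cell_id, sweeps = sweeps, protocol = protocol,
                 metadata = metadata), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> cell '%s': %d sweeps, protocol %s\n",
              x$cell_id, length(x$sweeps), x$protocol$kind))
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)
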