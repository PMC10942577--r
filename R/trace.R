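#' Construct a recorded trace
#'
#' A `trace` is a uniformly sampled signal: membrane potential in mV
#' (current-clamp) or clamp current in pA (voltage-clamp). Sample `i`
#' (0-based) occurs at `t0 + i * dt` milliseconds. Inward currents are
#' negative (EPSCs at depolarized holding potentials point down), outward
#' currents positive.
#'
#' @param values numeric vector of samples (mV or pA). Must be finite and
#'   non-empty.
#' @param dt sampling interval in ms (> 0).
#' @param t0 time of the first sample in ms.
#' @param signal_kind `"voltage"` or `"current"`.
#' @param condition free-form condition label (e.g. `"basal"`, `"XE991"`,
#'   `"gabazine"`).
#' @param cell_id cell identifier.
#' @param genotype `"WT"`, `"KO"` or `"NA"`.
#' @param protocol optional [protocol_spec] describing the applied stimulus.
#' @return an object of class `trace`.
#' @export
trace <- function(values, dt, t0 = 0, signal_kind = c("voltage", "current"),
                  condition = "basal", cell_id = "cell", genotype = "NA",
                  protocol = NULL) {
  signal_kind <- match.arg(signal_kind)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("trace: 'values' must be non-empty")
  if (!all(is.finite(values))) stop("trace: all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("trace: 'dt' must be a single positive number (ms)")
  if (!genotype %in% c("WT", "KO", "NA"))
    stop("trace: genotype must be WT, KO or NA")
  if (!is.null(protocol) && !inherits(protocol, "protocol_spec"))
    stop("trace: 'protocol' must be a protocol_spec or NULL")
  structure(
    list(values = values, dt = as.numeric(dt), t0 = as.numeric(t0),
         signal_kind = signal_kind, condition = condition,
         cell_id = cell_id, genotype = genotype, protocol = protocol),
    class = "trace")
}

#' Sample times of a trace
#' @param x a [trace].
#' @return numeric vector of times in ms, one per sample.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace: %s, %d samples @ dt=%g ms (%.3g s), cell=%s, cond=%s>\n",
              x$signal_kind, length(x$values), x$dt,
              length(x$values) * x$dt / 1000, x$cell_id, x$condition))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Stimulus protocol descriptions
#'
#' Declarative description of the stimulus applied during a trace: a current
#' step, a current ramp (optionally with a hyperpolarizing onset offset), a
#' family of steps, or an extracellular stimulus train. Exactly the fields of
#' the declared kind are populated.
#'
#' @param kind one of `"step"`, `"ramp"`, `"multistep"`, `"stim_train"`.
#' @param step_amplitude step amplitude, pA.
#' @param step_onset,step_duration step timing, ms.
#' @param ramp_rate ramp slope, pA/ms (current clamp) or mV/ms (voltage
#'   clamp).
#' @param ramp_onset time at which the ramp starts, ms.
#' @param ramp_pre_offset constant (typically hyperpolarizing, i.e. negative)
#'   current applied from `ramp_onset` onward, pA; the ramp rides on top of
#'   it so the injected current crosses 0 pA at
#'   `ramp_onset - ramp_pre_offset / ramp_rate`.
#' @param steps vector of step amplitudes (pA) for `multistep`.
#' @param stim_times strictly increasing stimulus times, ms.
#' @param holding_potential holding potential, mV (metadata).
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("step", "ramp", "multistep", "stim_train"),
                          step_amplitude = NULL, step_onset = NULL,
                          step_duration = NULL, ramp_rate = NULL,
                          ramp_onset = NULL, ramp_pre_offset = 0,
                          steps = NULL, stim_times = NULL,
                          holding_potential = NULL) {
  kind <- match.arg(kind)
  p <- switch(kind,
    step = {
      if (is.null(step_amplitude) || is.null(step_onset) ||
          is.null(step_duration))
        stop("step protocol needs step_amplitude, step_onset, step_duration")
      list(kind = kind, step_amplitude = step_amplitude,
           step_onset = step_onset, step_duration = step_duration)
    },
    ramp = {
      if (is.null(ramp_rate) || is.null(ramp_onset))
        stop("ramp protocol needs ramp_rate and ramp_onset")
      list(kind = kind, ramp_rate = ramp_rate, ramp_onset = ramp_onset,
           ramp_pre_offset = ramp_pre_offset)
    },
    multistep = {
      if (is.null(steps) || is.null(step_onset) || is.null(step_duration))
        stop("multistep protocol needs steps, step_onset, step_duration")
      list(kind = kind, steps = as.numeric(steps), step_onset = step_onset,
           step_duration = step_duration)
    },
    stim_train = {
      if (is.null(stim_times)) stop("stim_train protocol needs stim_times")
      stim_times <- as.numeric(stim_times)
      if (length(stim_times) > 1 && any(diff(stim_times) <= 0))
        stop("stim_times must be strictly increasing")
      list(kind = kind, stim_times = stim_times)
    })
  p$holding_potential <- holding_potential
  structure(p, class = "protocol_spec")
}

#' Injected-current waveform of a protocol
#'
#' Renders the command current (pA) sample-by-sample for step, ramp and
#' multistep protocols, on the same time base as a trace.
#'
#' @param protocol a [protocol_spec] of kind step, ramp or multistep.
#' @param n number of samples.
#' @param dt sampling interval, ms.
#' @param t0 time of the first sample, ms.
#' @param step_index which amplitude of a multistep family to render.
#' @return numeric vector of length `n` (pA).
#' @export
protocol_current <- function(protocol, n, dt, t0 = 0, step_index = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"))
  t <- t0 + (seq_len(n) - 1) * dt
  switch(protocol$kind,
    step = ifelse(t >= protocol$step_onset &
                  t < protocol$step_onset + protocol$step_duration,
                  protocol$step_amplitude, 0),
    ramp = ifelse(t >= protocol$ramp_onset,
                  protocol$ramp_pre_offset +
                    protocol$ramp_rate * (t - protocol$ramp_onset), 0),
    multistep = ifelse(t >= protocol$step_onset &
                       t < protocol$step_onset + protocol$step_duration,
                       protocol$steps[[step_index]], 0),
    stop("protocol_current: no current waveform for kind ", protocol$kind))
}

#' Bundle one cell's recordings
#'
#' @param cell_id cell identifier.
#' @param genotype `"WT"`, `"KO"` or `"NA"`.
#' @param cell_type `"MC"` (mossy cell), `"GC"` (granule cell), `"IN"`
#'   (hilar interneuron) or `"unknown"`.
#' @param capacitance membrane capacitance, pF (amplifier metadata; must be
#'   positive when given).
#' @param rmp resting membrane potential, mV.
#' @param traces list of [trace] objects; every trace's `cell_id` must match.
#' @return an object of class `cell_record`.
#' @export
cell_record <- function(cell_id, genotype = "NA",
                        cell_type = c("MC", "GC", "IN", "unknown"),
                        capacitance = NA_real_, rmp = NA_real_,
                        traces = list()) {
  cell_type <- match.arg(cell_type)
  if (!is.na(capacitance) && capacitance <= 0)
    stop("cell_record: capacitance must be > 0 when present")
  for (tr in traces) {
    stopifnot(inherits(tr, "trace"))
    if (!identical(tr$cell_id, cell_id))
      stop("cell_record: trace cell_id '", tr$cell_id,
           "' does not match '", cell_id, "'")
  }
  structure(list(cell_id = cell_id, genotype = genotype,
                 cell_type = cell_type, capacitance = capacitance,
                 rmp = rmp, traces = traces),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record %s: %s %s, C=%g pF, %d traces>\n",
              x$cell_id, x$genotype, x$cell_type, x$capacitance,
              length(x$traces)))
  invisible(x)
}
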