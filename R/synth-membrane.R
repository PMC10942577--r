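# Synthetic membrane: a single-compartment spiking model used as ground
# truth for the current-clamp analyses. Subthreshold behaviour is a leaky
# membrane plus one slow Kv7-like K+ conductance (first-order gate with
# Boltzmann steady state); spikes arise from an exponential-onset,
# saturating Na-like current with slow inactivation, repolarized by a
# delayed-rectifier gate, so emitted traces carry full action-potential
# waveforms (threshold, upstroke, peak, downstroke) that the feature
# extractors can measure.

#' Membrane model parameters
#'
#' Defaults describe a mossy-cell-like neuron: C = 150 pF, input resistance
#' about 150 Mohm, rest near -65 mV, Kv7 half-activation -40 mV with 8 mV
#' slope. The KO profile differs from WT only by scaling `g_kv7_max`.
#'
#' @param C capacitance, pF.
#' @param g_leak leak conductance, nS (6.7 nS gives ~150 Mohm).
#' @param E_leak leak reversal, mV.
#' @param g_kv7_max maximal Kv7 conductance, nS.
#' @param kv7_vhalf,kv7_k Kv7 activation half-voltage and slope, mV.
#' @param tau_kv7 Kv7 activation time constant, ms (0 = instantaneous
#'   Boltzmann conductance).
#' @param E_K potassium reversal, mV.
#' @param g_na,E_na spike-current maximal conductance (nS) and reversal (mV).
#' @param vm_half half-activation of the spike current, mV; together with
#'   `delta_t` it sets the emergent voltage threshold (~ -45 mV at default
#'   load).
#' @param delta_t spike-onset slope, mV: the low-voltage tail of the spike
#'   current grows as exp(V/delta_t), as in exponential integrate-and-fire
#'   models.
#' @param g_kd,vn_half,kn,tau_n delayed-rectifier conductance (nS), gate
#'   half-voltage (mV), slope (mV) and time constant (ms).
#' @param vh_half,kh Na inactivation half-voltage and slope, mV.
#' @param tau_h_rest,tau_h_spike inactivation time constants near rest and
#'   at spike voltages, ms.
#' @param noise_sigma stationary SD of the Ornstein-Uhlenbeck current noise,
#'   pA (0 = noise-free).
#' @param tau_ou correlation time of the current noise, ms.
#' @param genotype label stored with generated traces.
#' @return a named list of class `membrane_params`.
#' @export
membrane_params <- function(C = 150, g_leak = 6.7, E_leak = -65,
                            g_kv7_max = 6, kv7_vhalf = -40, kv7_k = 8,
                            tau_kv7 = 50, E_K = -90,
                            g_na = 1000, E_na = 50, vm_half = -34,
                            delta_t = 2,
                            g_kd = 200, vn_half = -25, kn = 4, tau_n = 3,
                            vh_half = -38, kh = 5,
                            tau_h_rest = 20, tau_h_spike = 1,
                            noise_sigma = 0, tau_ou = 5, genotype = "NA") {
  stopifnot(C > 0, g_leak > 0, delta_t > 0, kv7_k > 0, tau_kv7 >= 0)
  structure(as.list(environment()), class = "membrane_params")
}

#' KO-profile parameters: WT scaled by a Kv7 conductance factor
#'
#' @param wt a [membrane_params].
#' @param kv7_scale multiplicative factor (>= 1) applied to `g_kv7_max`.
#' @return a [membrane_params] labelled `"KO"`.
#' @export
ko_params <- function(wt = membrane_params(genotype = "WT"),
                      kv7_scale = 1.5) {
  stopifnot(kv7_scale >= 1)
  p <- wt
  p$g_kv7_max <- wt$g_kv7_max * kv7_scale
  p$genotype <- "KO"
  p
}

# steady-state gate values at voltage v
gate_inf <- function(params, v) {
  list(a = 1 / (1 + exp((params$kv7_vhalf - v) / params$kv7_k)),
       n = 1 / (1 + exp((params$vn_half - v) / params$kn)),
       h = 1 / (1 + exp((v - params$vh_half) / params$kh)))
}

# total steady-state membrane current (pA, outward positive) at voltage v
steady_current <- function(params, v) {
  g <- gate_inf(params, v)
  m <- 1 / (1 + exp((params$vm_half - v) / params$delta_t))
  params$g_leak * (v - params$E_leak) +
    params$g_kv7_max * g$a * (v - params$E_K) +
    params$g_kd * g$n * (v - params$E_K) +
    params$g_na * m * g$h * (v - params$E_na)
}

#' Holding current needed to rest a model cell at a target potential
#' @param params a [membrane_params].
#' @param v target membrane potential, mV (subthreshold).
#' @return holding current, pA.
#' @export
holding_current_for <- function(params, v) steady_current(params, v)

#' Steady-state subthreshold potential under constant current
#' @param params a [membrane_params].
#' @param I injected current, pA.
#' @param interval search interval, mV.
#' @return membrane potential, mV.
#' @export
steady_state_v <- function(params, I, interval = c(-100, -35)) {
  f <- function(v) steady_current(params, v) - I
  # lowest root: scan for the first sign change from the hyperpolarized end
  grid <- seq(interval[1], interval[2], by = 0.5)
  fg <- vapply(grid, f, numeric(1))
  ix <- which(fg[-length(fg)] * fg[-1] <= 0)
  if (!length(ix))
    stop("steady_state_v: no subthreshold steady state in the interval")
  stats::uniroot(f, interval = grid[c(ix[1], ix[1] + 1)], tol = 1e-10)$root
}

#' Simulate a current-clamp recording
#'
#' Integrates the membrane model under a step, ramp or multistep protocol
#' (fixed-step RK4 on the voltage, exact exponential relaxation for the
#' gates) and returns the voltage trace plus ground truth. Current noise is
#' an Ornstein-Uhlenbeck process; the run is deterministic given `seed`.
#'
#' @param params a [membrane_params].
#' @param protocol a [protocol_spec] of kind step, ramp or multistep.
#' @param duration_ms total simulated time, ms.
#' @param dt integration/sampling step, ms (<= 0.05).
#' @param seed RNG seed.
#' @param holding_current constant current added throughout (pA), e.g. to
#'   set the pre-stimulus potential.
#' @param step_index which multistep amplitude to run.
#' @param cell_id,condition trace metadata.
#' @return a list with `trace` (voltage [trace]) and `truth` (list with
#'   `spike_times` in ms, the injected-current vector, and the parameter
#'   set).
#' @export
simulate_membrane <- function(params, protocol, duration_ms, dt = 0.02,
                              seed = 1, holding_current = 0,
                              step_index = 1L, cell_id = "synth",
                              condition = "basal") {
  stopifnot(inherits(params, "membrane_params"),
            inherits(protocol, "protocol_spec"))
  if (!protocol$kind %in% c("step", "ramp", "multistep"))
    stop("simulate_membrane: protocol kind must be step, ramp or multistep")
  if (dt > 0.05) stop("simulate_membrane: dt must be <= 0.05 ms")
  n <- as.integer(round(duration_ms / dt)) + 1L
  I <- protocol_current(protocol, n, dt, step_index = step_index) +
    holding_current
  v0 <- steady_state_v(params, holding_current)
  g0 <- gate_inf(params, v0)
  res <- withr::with_seed(seed,
    simulate_membrane_cpp(I, dt, unclass(params), v0, g0$a, g0$n, g0$h,
                          params$noise_sigma, params$tau_ou))
  tr <- trace(res$v, dt = dt, signal_kind = "voltage",
              condition = condition, cell_id = cell_id,
              genotype = params$genotype, protocol = protocol)
  list(trace = tr,
       truth = list(spike_times = res$spike_times, injected_current = I,
                    params = params, seed = seed))
}

#' Simulate a voltage-clamp ramp recording
#'
#' Clamp current in response to a voltage-command ramp: leak plus the Kv7
#' current with its first-order activation lag (or the instantaneous
#' Boltzmann conductance when `tau_kv7 = 0`). `kv7_blocked = TRUE` emulates
#' a saturating XE991 application by removing the Kv7 conductance.
#'
#' @param params a [membrane_params]; only leak and Kv7 fields are used
#'   (spike and delayed-rectifier currents are absent, as under TTX/Cd2+).
#' @param ramp a [protocol_spec] of kind `"ramp"` in mV/ms with
#'   `ramp_pre_offset` read as the starting command voltage (mV).
#' @param duration_ms total simulated time, ms.
#' @param dt sampling step, ms.
#' @param kv7_blocked if TRUE the Kv7 conductance is set to zero.
#' @param noise_sd Gaussian current noise SD, pA.
#' @param seed RNG seed.
#' @param cell_id,condition trace metadata.
#' @return list with `trace` (current [trace]), `command` (voltage [trace])
#'   and `truth` (list with the noise-free leak and Kv7 current components).
#' @export
simulate_vc_ramp <- function(params, ramp, duration_ms, dt = 0.02,
                             kv7_blocked = FALSE, noise_sd = 0, seed = 1,
                             cell_id = "synth",
                             condition = if (kv7_blocked) "XE991" else "basal") {
  stopifnot(inherits(params, "membrane_params"),
            inherits(ramp, "protocol_spec"))
  if (ramp$kind != "ramp") stop("simulate_vc_ramp: protocol must be a ramp")
  n <- as.integer(round(duration_ms / dt)) + 1L
  t <- (seq_len(n) - 1) * dt
  v_cmd <- ramp$ramp_pre_offset +
    ifelse(t >= ramp$ramp_onset, ramp$ramp_rate * (t - ramp$ramp_onset), 0)
  i_leak <- params$g_leak * (v_cmd - params$E_leak)
  a_inf <- 1 / (1 + exp((params$kv7_vhalf - v_cmd) / params$kv7_k))
  if (params$tau_kv7 > 0) {
    lambda <- exp(-dt / params$tau_kv7)
    a <- as.numeric(stats::filter((1 - lambda) * a_inf, lambda,
                                  method = "recursive",
                                  init = a_inf[1]))
  } else {
    a <- a_inf
  }
  g_kv7 <- if (kv7_blocked) 0 else params$g_kv7_max
  i_kv7 <- g_kv7 * a * (v_cmd - params$E_K)
  i <- i_leak + i_kv7
  if (noise_sd > 0)
    i <- i + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(trace = trace(i, dt = dt, signal_kind = "current",
                     condition = condition, cell_id = cell_id,
                     genotype = params$genotype, protocol = ramp),
       command = trace(v_cmd, dt = dt, signal_kind = "voltage",
                       condition = condition, cell_id = cell_id,
                       genotype = params$genotype),
       truth = list(i_leak = i_leak, i_kv7 = i_kv7, params = params))
}
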