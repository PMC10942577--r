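# Synthetic theta-gamma stimulation trials: Bernoulli spike responses to a
# 5 Hz theta train, with spike probability transiently suppressed by a
# preceding 50 Hz gamma burst, optionally rendered as voltage traces.

#' Stereotyped action-potential waveform
#'
#' Smooth unit waveform (difference of sigmoids) used when rendering
#' synthetic voltage traces that must carry detectable spikes; peak value 1
#' at roughly `t = 0.9` ms from onset, width ~1 ms.
#'
#' @param t times from AP onset, ms.
#' @return numeric vector, unit peak.
#' @keywords internal
ap_waveform <- function(t) {
  w <- 1 / (1 + exp(-(t - 0.6) / 0.12)) - 1 / (1 + exp(-(t - 1.4) / 0.30))
  w[t < 0] <- 0
  w / 0.90929
}

#' Simulate theta-gamma stimulation trials
#'
#' Per theta stimulus a spike occurs with probability `p`, where `p =
#' p_base` in the control train and, after a gamma burst, `p = p_base *
#' (s + (1 - s) * (1 - exp(-t / tau_rec)))` with `t` the time from theta
#' onset (suppression factor `s` recovering with time constant `tau_rec`;
#' `tau_rec = Inf` holds the suppression constant). Subthreshold EPSP
#' amplitudes are scaled by the same factor.
#'
#' @param p_base baseline spike probability per theta stimulus, in \[0, 1\].
#' @param s suppression factor in \[0, 1\] (1 = no suppression).
#' @param n_trials number of trials (>= 1).
#' @param with_gamma if TRUE the gamma burst precedes the theta train (the
#'   "test" protocol); otherwise the control protocol is used.
#' @param tau_rec recovery time constant, ms.
#' @param seed RNG seed.
#' @param render if TRUE, also return one voltage [trace] per trial
#'   (baseline -70 mV, EPSP per stimulus, stereotyped AP when the raster
#'   says the stimulus evoked one).
#' @param dt rendering sample interval, ms.
#' @param epsp_amp unsuppressed EPSP amplitude, mV.
#' @param ap_latency,ap_amp AP onset latency after the stimulus (ms) and
#'   height above baseline (mV).
#' @param cell_id,genotype metadata for rendered traces.
#' @return list with `protocol` (stim_train [protocol_spec]), `raster`
#'   (n_trials x n_theta 0/1 matrix), `truth` (per-stimulus probability and
#'   EPSP scale), and `traces` when rendered.
#' @export
simulate_theta_gamma <- function(p_base = 0.5, s = 0.4, n_trials = 20,
                                 with_gamma = TRUE, tau_rec = 1000,
                                 seed = 1, render = FALSE, dt = 0.1,
                                 epsp_amp = 8, ap_latency = 4, ap_amp = 105,
                                 cell_id = "synth", genotype = "NA") {
  stopifnot(p_base >= 0, p_base <= 1, s >= 0, s <= 1, n_trials >= 1)
  protocol <- build_stim_protocol(if (with_gamma) "test" else "control")
  theta_times <- protocol$stim_times[protocol$stim_times >= 0]
  n_theta <- length(theta_times)
  factor_at <- function(t) {
    if (!with_gamma) return(rep(1, length(t)))
    if (is.infinite(tau_rec)) rep(s, length(t))
    else s + (1 - s) * (1 - exp(-t / tau_rec))
  }
  fac <- factor_at(theta_times)
  p <- p_base * fac
  raster <- withr::with_seed(seed,
    matrix(stats::rbinom(n_trials * n_theta, 1, rep(p, each = n_trials)),
           nrow = n_trials, ncol = n_theta))
  out <- list(protocol = protocol, raster = raster,
              truth = list(p = p, epsp_scale = fac,
                           theta_times = theta_times, p_base = p_base,
                           s = s, tau_rec = tau_rec, seed = seed))
  if (render) {
    t_start <- min(protocol$stim_times) - 100
    t_end <- max(theta_times) + 150
    tt <- seq(t_start, t_end, by = dt)
    gamma_times <- protocol$stim_times[protocol$stim_times < 0]
    epsp <- function(t) biexp_kernel(t, 4, 40)
    out$traces <- lapply(seq_len(n_trials), function(tr) {
      v <- rep(-70, length(tt))
      for (g in gamma_times) v <- v + epsp_amp * epsp(tt - g - 1)
      for (k in seq_len(n_theta)) {
        st <- theta_times[k]
        if (raster[tr, k] == 1) {
          v <- v + ap_amp * ap_waveform(tt - st - ap_latency)
          v <- v + 0.3 * epsp_amp * fac[k] * epsp(tt - st - 1)
        } else {
          v <- v + epsp_amp * fac[k] * epsp(tt - st - 1)
        }
      }
      trace(v, dt = dt, t0 = t_start, signal_kind = "voltage",
            condition = if (with_gamma) "test" else "control",
            cell_id = cell_id, genotype = genotype, protocol = protocol)
    })
  }
  out
}
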