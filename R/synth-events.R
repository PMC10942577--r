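# Synthetic synaptic-current generators: Poisson trains of biexponential
# postsynaptic currents with lognormal amplitudes, and stimulus-evoked
# compound PSCs assembled from known EPSC and IPSC components.

#' Biexponential PSC kernel, normalized to unit peak
#'
#' `k(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / k_peak` for `t >= 0`, where
#' `k_peak` makes the maximum exactly 1, so an event of amplitude A reaches
#' a signed extremum of exactly A.
#'
#' @param t times from event onset, ms (values < 0 give 0).
#' @param tau_r,tau_d rise and decay time constants, ms (`tau_d > tau_r`).
#' @return numeric vector of kernel values in \[0, 1\].
#' @export
biexp_kernel <- function(t, tau_r = 0.5, tau_d = 5) {
  stopifnot(tau_d > tau_r, tau_r > 0)
  t_peak <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  peak <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_d) - exp(-t[pos] / tau_r)) / peak
  out
}

#' Event-train generator parameters
#'
#' @param rate Poisson event rate, Hz (>= 0).
#' @param duration trace duration, s.
#' @param amp_meanlog,amp_sdlog lognormal amplitude-magnitude parameters
#'   (pA); defaults give a median of ~30 pA.
#' @param amp_min lower clip on amplitude magnitude, pA.
#' @param tau_r,tau_d kernel rise and decay time constants, ms.
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param noise_sd Gaussian recording-noise SD, pA.
#' @param dt sampling interval, ms.
#' @return a named list of class `event_train_params`.
#' @export
event_train_params <- function(rate = 10, duration = 30,
                               amp_meanlog = log(30), amp_sdlog = 0.25,
                               amp_min = 12, tau_r = 0.5, tau_d = 5,
                               polarity = c("inward", "outward"),
                               noise_sd = 2, dt = 0.1) {
  polarity <- match.arg(polarity)
  stopifnot(rate >= 0, duration > 0, tau_d > tau_r, tau_r > 0, dt > 0)
  structure(as.list(environment()), class = "event_train_params")
}

#' Generate a spontaneous-PSC current trace with known ground truth
#'
#' Event times are homogeneous Poisson; each event adds a unit-peak
#' biexponential kernel scaled by a lognormal amplitude; Gaussian noise is
#' added on top. Truth lists the exact times and signed amplitudes.
#'
#' @param params an [event_train_params].
#' @param seed RNG seed.
#' @param cell_id,condition,genotype trace metadata.
#' @return list with `trace` (current [trace]) and `truth` (data frame of
#'   `time_ms`, `amplitude_pa`).
#' @export
generate_event_train <- function(params, seed = 1, cell_id = "synth",
                                 condition = "basal", genotype = "NA") {
  stopifnot(inherits(params, "event_train_params"))
  dur_ms <- params$duration * 1000
  if (params$rate * params$duration > 1e6)
    stop("generate_event_train: rate * duration exceeds 1e6 events")
  n <- as.integer(round(dur_ms / params$dt)) + 1L
  sgn <- if (params$polarity == "inward") -1 else 1
  out <- withr::with_seed(seed, {
    n_ev <- stats::rpois(1, params$rate * params$duration)
    times <- sort(stats::runif(n_ev, 0, dur_ms))
    amps <- pmax(stats::rlnorm(n_ev, params$amp_meanlog, params$amp_sdlog),
                 params$amp_min)
    noise <- if (params$noise_sd > 0)
      stats::rnorm(n, 0, params$noise_sd) else numeric(n)
    list(times = times, amps = amps, noise = noise)
  })
  values <- out$noise
  # kernel support: ~8 decay constants
  klen <- min(n, as.integer(ceiling(8 * params$tau_d / params$dt)))
  kern <- biexp_kernel((seq_len(klen) - 1) * params$dt,
                       params$tau_r, params$tau_d)
  for (k in seq_along(out$times)) {
    i0 <- as.integer(floor(out$times[k] / params$dt)) + 1L
    idx <- i0:min(n, i0 + klen - 1L)
    toff <- (idx - 1) * params$dt - out$times[k]
    values[idx] <- values[idx] +
      sgn * out$amps[k] * biexp_kernel(toff, params$tau_r, params$tau_d)
  }
  truth <- data.frame(time_ms = out$times, amplitude_pa = sgn * out$amps)
  list(trace = trace(values, dt = params$dt, signal_kind = "current",
                     condition = condition, cell_id = cell_id,
                     genotype = genotype),
       truth = truth)
}

#' Compose stimulus-evoked compound PSC sweeps with known components
#'
#' Each sweep is an EPSC kernel (inward, latency `epsc_latency`) plus an
#' IPSC kernel (outward, later latency) plus noise, with the stimulus at
#' t = 0 and a pre-stimulus baseline segment. Also emits isolated EPSC-only
#' sweeps (the "gabazine" condition) for template construction. Per-sweep
#' amplitudes are jittered by a common multiplicative factor per component.
#'
#' @param epsc_peak EPSC peak, pA (< 0).
#' @param ipsc_peak IPSC peak, pA (>= 0).
#' @param epsc_latency,ipsc_latency kernel onset latencies after the
#'   stimulus, ms (`ipsc_latency > epsc_latency`).
#' @param epsc_tau,ipsc_tau length-2 vectors `c(tau_r, tau_d)` in ms.
#' @param n_sweeps number of compound sweeps.
#' @param n_template number of EPSC-only template sweeps (>= 20 for the
#'   template builder).
#' @param amp_cv multiplicative amplitude jitter CV per sweep and component.
#' @param noise_sd Gaussian noise SD, pA.
#' @param pre_ms,post_ms baseline before and window after the stimulus, ms.
#' @param dt sampling interval, ms.
#' @param seed RNG seed.
#' @param cell_id,genotype metadata.
#' @return list with `cpsc_sweeps` (list of current [trace]s, `t0 = -pre_ms`),
#'   `template_sweeps` (EPSC-only sweeps), and `truth` (noise-free mean EPSC,
#'   IPSC and cPSC waveforms on the same time base, plus per-sweep scale
#'   factors).
#' @export
compose_cpsc <- function(epsc_peak = -120, ipsc_peak = 80,
                         epsc_latency = 2, ipsc_latency = 4,
                         epsc_tau = c(0.5, 6), ipsc_tau = c(1.5, 15),
                         n_sweeps = 25, n_template = 25, amp_cv = 0.1,
                         noise_sd = 3, pre_ms = 50, post_ms = 150,
                         dt = 0.05, seed = 1, cell_id = "synth",
                         genotype = "NA") {
  stopifnot(epsc_peak < 0, ipsc_peak >= 0, ipsc_latency > epsc_latency)
  t <- seq(-pre_ms, post_ms, by = dt)
  e_kern <- biexp_kernel(t - epsc_latency, epsc_tau[1], epsc_tau[2])
  i_kern <- biexp_kernel(t - ipsc_latency, ipsc_tau[1], ipsc_tau[2])
  n <- length(t)
  res <- withr::with_seed(seed, {
    se <- if (amp_cv > 0) stats::rnorm(n_sweeps, 1, amp_cv) else rep(1, n_sweeps)
    si <- if (amp_cv > 0) stats::rnorm(n_sweeps, 1, amp_cv) else rep(1, n_sweeps)
    st <- if (amp_cv > 0) stats::rnorm(n_template, 1, amp_cv) else rep(1, n_template)
    mk <- function(vals) vals +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    cp <- lapply(seq_len(n_sweeps), function(k)
      mk(se[k] * epsc_peak * e_kern + si[k] * ipsc_peak * i_kern))
    tp <- lapply(seq_len(n_template), function(k)
      mk(st[k] * epsc_peak * e_kern))
    list(se = se, si = si, st = st, cp = cp, tp = tp)
  })
  as_tr <- function(vals, cond) trace(vals, dt = dt, t0 = -pre_ms,
                                      signal_kind = "current",
                                      condition = cond, cell_id = cell_id,
                                      genotype = genotype)
  truth <- list(time_ms = t,
                epsc = mean(res$se) * epsc_peak * e_kern,
                ipsc = mean(res$si) * ipsc_peak * i_kern,
                epsc_scales = res$se, ipsc_scales = res$si,
                template_scales = res$st,
                epsc_peak = epsc_peak, ipsc_peak = ipsc_peak)
  truth$cpsc <- truth$epsc + truth$ipsc
  list(cpsc_sweeps = lapply(res$cp, as_tr, cond = "basal"),
       template_sweeps = lapply(res$tp, as_tr, cond = "gabazine"),
       truth = truth)
}
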