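# Theta-gamma stimulation analysis: stimulus protocols, per-stimulus AP
# detection, AP probability in 1 s bins, EPSP amplitudes, and the
# gamma-suppression comparison.

#' Build a theta / theta-gamma stimulation protocol
#'
#' Control: `n_theta` stimuli at `theta_hz` starting at t = 0. Test: a
#' burst of `n_gamma` stimuli at `gamma_hz` whose last stimulus falls
#' `lead_ms` before theta onset, followed by the same theta train.
#'
#' @param kind `"control"` or `"test"`.
#' @param theta_hz,n_theta theta train frequency (Hz) and length.
#' @param gamma_hz,n_gamma gamma burst frequency (Hz) and length.
#' @param lead_ms gap between the last gamma stimulus and theta onset, ms.
#' @return a stim_train [protocol_spec].
#' @export
build_stim_protocol <- function(kind = c("control", "test"), theta_hz = 5,
                                n_theta = 15, gamma_hz = 50, n_gamma = 5,
                                lead_ms = 200) {
  kind <- match.arg(kind)
  stopifnot(theta_hz > 0, n_theta > 0, gamma_hz > 0, n_gamma > 0,
            lead_ms > 0)
  theta <- (seq_len(n_theta) - 1) * 1000 / theta_hz
  times <- if (kind == "control") theta else {
    gamma <- -lead_ms - rev(seq_len(n_gamma) - 1) * 1000 / gamma_hz
    c(gamma, theta)
  }
  protocol_spec("stim_train", stim_times = times)
}

#' Per-stimulus AP probability in 1 s bins
#'
#' A theta stimulus counts as having evoked an AP when [detect_aps] finds a
#' spike within `window_ms` after it. Probabilities are reported per 1 s
#' bin of the theta train (5 stimuli per bin at 5 Hz); gamma-burst stimuli
#' (negative times) are excluded.
#'
#' @param traces list of voltage [trace]s, one per trial, sharing the
#'   protocol.
#' @param protocol a stim_train [protocol_spec]; defaults to the first
#'   trace's.
#' @param window_ms response-attribution window after each stimulus, ms.
#' @param bin_s bin width, s.
#' @param min_trials below this trial count a low-trial warning is raised
#'   (the result is still computed).
#' @param ... passed to [detect_aps].
#' @return object of class `stim_train_result`: `per_stim` data frame
#'   (`stim_time_ms`, `bin`, `p`), `bins` data frame (`bin`, `p`,
#'   `evoked`, `n`), `raster` (trials x stimuli 0/1), `n_trials`,
#'   `protocol`.
#' @export
ap_probability_binned <- function(traces, protocol = traces[[1]]$protocol,
                                  window_ms = 50, bin_s = 1,
                                  min_trials = 10, ...) {
  stopifnot(length(traces) >= 1, inherits(protocol, "protocol_spec"),
            protocol$kind == "stim_train")
  if (length(traces) < min_trials)
    warning("ap_probability_binned: only ", length(traces),
            " trials (>= ", min_trials, " recommended)")
  theta <- protocol$stim_times[protocol$stim_times >= 0]
  raster <- t(vapply(traces, function(tr) {
    spikes <- detect_aps(tr, ...)$peak_time_ms
    vapply(theta, function(st)
      as.integer(any(spikes > st & spikes <= st + window_ms)), integer(1))
  }, integer(length(theta))))
  raster_binned_result(raster, theta, protocol, bin_s)
}

# shared tail of ap_probability_binned / raster-based entry point
raster_binned_result <- function(raster, theta, protocol, bin_s = 1) {
  bin <- floor(theta / (1000 * bin_s)) + 1L
  p_stim <- colMeans(raster)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, p = mean(raster[, sel, drop = FALSE]),
               evoked = sum(raster[, sel, drop = FALSE]),
               n = sum(sel) * nrow(raster))
  }))
  structure(list(per_stim = data.frame(stim_time_ms = theta, bin = bin,
                                       p = p_stim),
                 bins = bins, raster = raster, n_trials = nrow(raster),
                 protocol = protocol),
            class = "stim_train_result")
}

#' Binned AP probability from a spike raster
#'
#' Entry point for raster data (e.g. the synthetic theta-gamma generator's
#' output) rather than voltage traces.
#'
#' @param raster trials x theta-stimuli 0/1 matrix.
#' @param protocol a stim_train [protocol_spec].
#' @param bin_s bin width, s.
#' @return a `stim_train_result` (see [ap_probability_binned]).
#' @export
ap_probability_from_raster <- function(raster, protocol, bin_s = 1) {
  theta <- protocol$stim_times[protocol$stim_times >= 0]
  stopifnot(ncol(raster) == length(theta))
  raster_binned_result(as.matrix(raster), theta, protocol, bin_s)
}

#' EPSP amplitudes per theta stimulus
#'
#' For stimuli that did not evoke an AP, the EPSP amplitude is the peak
#' voltage within `window_ms` after the stimulus minus the pre-train
#' baseline (mean over `baseline_ms` before the earliest stimulus).
#' Stimuli with an AP in the window are excluded (NA, flagged).
#'
#' @param traces list of voltage [trace]s (trials).
#' @param protocol a stim_train [protocol_spec].
#' @param window_ms response window, ms.
#' @param baseline_ms baseline-averaging window, ms.
#' @param ... passed to [detect_aps].
#' @return data frame: `stim_time_ms`, `mean_epsp_mv` (across trials,
#'   AP-contaminated trials excluded), `n_ok`, `n_excluded`.
#' @export
epsp_amplitudes <- function(traces, protocol = traces[[1]]$protocol,
                            window_ms = 50, baseline_ms = 50, ...) {
  stopifnot(length(traces) >= 1, inherits(protocol, "protocol_spec"))
  theta <- protocol$stim_times[protocol$stim_times >= 0]
  first_stim <- min(protocol$stim_times)
  per_trial <- lapply(traces, function(tr) {
    t <- trace_times(tr)
    base <- mean(tr$values[t >= first_stim - baseline_ms & t < first_stim])
    spikes <- detect_aps(tr, ...)$peak_time_ms
    vapply(theta, function(st) {
      if (any(spikes > st & spikes <= st + window_ms)) return(NA_real_)
      sel <- t > st & t <= st + window_ms
      max(tr$values[sel]) - base
    }, numeric(1))
  })
  amp <- do.call(rbind, per_trial)
  data.frame(stim_time_ms = theta,
             mean_epsp_mv = colMeans(amp, na.rm = TRUE),
             n_ok = colSums(!is.na(amp)),
             n_excluded = colSums(is.na(amp)))
}

#' Gamma-suppression comparison between control and test trains
#'
#' Per-bin probability difference `p_test - p_control` and ratio
#' `p_test / p_control` (undefined where the control probability is 0);
#' the headline comparison is the first-second bin.
#'
#' @param control,test `stim_train_result`s with matching bins.
#' @return data frame: `bin`, `p_control`, `p_test`, `delta_p`, `ratio`.
#' @export
gamma_suppression_index <- function(control, test) {
  stopifnot(inherits(control, "stim_train_result"),
            inherits(test, "stim_train_result"))
  if (!identical(control$bins$bin, test$bins$bin))
    stop("gamma_suppression_index: bin structures differ")
  pc <- control$bins$p; pt <- test$bins$p
  data.frame(bin = control$bins$bin, p_control = pc, p_test = pt,
             delta_p = pt - pc,
             ratio = ifelse(pc > 0, pt / pc, NA_real_))
}
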