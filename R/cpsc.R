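# Compound-PSC decomposition: EPSC template from pharmacologically isolated
# sweeps, approximating-segment scaling, underlying EPSC/IPSC isolation,
# excitation window, and E/I ratios by peak and by 100 ms charge transfer.

# baseline-correct one sweep: subtract the mean of `pre_ms` before the
# stimulus (stimulus at t = 0 on the trace time base)
sweep_baseline <- function(x, pre_ms = 5) {
  t <- trace_times(x)
  sel <- t >= -pre_ms & t < 0
  if (!any(sel)) stop("sweep has no pre-stimulus baseline samples")
  x$values - mean(x$values[sel])
}

# centered boxcar mean (window k samples), edges padded by replication
run_mean <- function(v, k) {
  if (k < 2) return(v)
  half <- k %/% 2
  vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
  cs <- cumsum(vp)
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

# contamination QC on a 1 ms-smoothed sweep: an event-like excursion in the
# pre-stimulus window, or a secondary inward rise on the decay that climbs
# back by more than the detection threshold and sec_frac of the main peak
sweep_contaminated <- function(x, pre_ms = 50, threshold_pa = 10,
                               sec_frac = 0.25, smooth_ms = 1) {
  v <- sweep_baseline(x, pre_ms = min(5, pre_ms))
  k <- max(1L, as.integer(round(smooth_ms / x$dt)))
  ws <- run_mean(v, k)
  t <- trace_times(x)
  pre <- ws[t >= -pre_ms & t < 0]
  if (length(pre) && any(abs(pre - stats::median(pre)) > threshold_pa))
    return(TRUE)
  post <- ws[t >= 0]
  if (length(post) < 5) return(FALSE)
  ip <- which.min(post)
  main <- -post[ip]
  if (main <= 0 || ip >= length(post) - 2) return(FALSE)
  # inward depth relative to the running minimum since the main peak
  decay <- -post[(ip + 1):length(post)]
  rebound <- decay - cummin(decay)
  any(decay > threshold_pa & rebound > max(threshold_pa, sec_frac * main))
}

#' Build an EPSC template from isolated-EPSC sweeps
#'
#' Sweeps are baseline-subtracted (mean of `baseline_ms` pre-stimulus) and
#' averaged; contaminated sweeps (pre-stimulus event or secondary peak on
#' the decay) are excluded. At least `min_events` clean sweeps are
#' required.
#'
#' @param sweeps list of current [trace]s with the stimulus at t = 0
#'   (i.e. `t0 < 0`).
#' @param min_events minimum number of clean sweeps (20 by convention).
#' @param baseline_ms pre-stimulus baseline window, ms.
#' @return object of class `epsc_template`: `waveform` (pA), `time_ms`,
#'   `n_events`, `peak_pa` (signed minimum), `peak_time_ms`, `dt`,
#'   `n_excluded`.
#' @export
build_epsc_template <- function(sweeps, min_events = 20, baseline_ms = 5) {
  stopifnot(length(sweeps) >= 1)
  contaminated <- vapply(sweeps, sweep_contaminated, logical(1))
  clean <- sweeps[!contaminated]
  if (length(clean) < min_events)
    stop("build_epsc_template: only ", length(clean),
         " uncontaminated sweeps (need >= ", min_events, ")")
  mat <- vapply(clean, sweep_baseline, numeric(length(clean[[1]]$values)),
                pre_ms = baseline_ms)
  wf <- rowMeans(mat)
  t <- trace_times(clean[[1]])
  ip <- which.min(wf)
  structure(list(waveform = wf, time_ms = t, n_events = length(clean),
                 peak_pa = wf[ip], peak_time_ms = t[ip],
                 dt = clean[[1]]$dt, n_excluded = sum(contaminated)),
            class = "epsc_template")
}

#' Approximating segment of a compound PSC
#'
#' Samples on the rising (downward-going) limb of the excitatory component
#' whose depth lies between `lo` and `hi` of the excitatory peak depth,
#' restricted to at most `cap_ms` after the stimulus.
#'
#' @param waveform baseline-corrected cPSC mean waveform, pA.
#' @param time_ms time base, ms (stimulus at 0).
#' @param lo,hi fractional depth bounds (0.25 and 0.65 by convention).
#' @param cap_ms latest allowed time after the stimulus, ms.
#' @return integer vector of sample indices (>= 2), or an error of class
#'   `segment_not_found` when the intersection is empty.
#' @export
find_approximating_segment <- function(waveform, time_ms, lo = 0.25,
                                       hi = 0.65, cap_ms = 2.5) {
  post <- which(time_ms > 0)
  if (!length(post) || min(waveform[post]) >= 0)
    stop(errorCondition("no downward excitatory component",
                        class = c("segment_not_found", "error")))
  ip <- post[which.min(waveform[post])]
  depth <- -waveform[ip]
  rising <- post[post <= ip]
  frac <- -waveform[rising] / depth
  sel <- rising[frac >= lo & frac <= hi & time_ms[rising] <= cap_ms]
  if (length(sel) < 2)
    stop(errorCondition(
      "approximating segment empty (25-65% depth within 2.5 ms)",
      class = c("segment_not_found", "error")))
  sel
}

#' Decompose compound PSCs into underlying EPSC and IPSC
#'
#' The cPSC mean is the baseline-subtracted sweep average. The EPSC
#' template is scaled to each sample of the approximating segment
#' (`s_i = cPSC(t_i) / template(t_i)`); the scaled templates are averaged
#' into the underlying EPSC, and the underlying IPSC is the sample-wise
#' difference `cPSC - EPSC`, so EPSC + IPSC = cPSC holds to machine
#' precision. Segment samples where the template is below `template_floor`
#' of its peak are dropped from scaling.
#'
#' @param sweeps list of cPSC current [trace]s (stimulus at t = 0).
#' @param template an `epsc_template` on the same time base.
#' @param template_floor minimum template magnitude, as a fraction of the
#'   template peak, for a segment sample to contribute a scale factor.
#' @param charge_window_ms integration window for the charge-based E/I
#'   ratio, ms.
#' @param qc if TRUE, contaminated sweeps are excluded (20-25 clean sweeps
#'   is the recommended range; a warning is raised outside it).
#' @param per_sweep if TRUE, scale factors are computed per sweep and
#'   averaged, instead of on the sweep-averaged cPSC.
#' @return object of class `cpsc_decomposition`: waveforms (`time_ms`,
#'   `cpsc`, `epsc`, `ipsc`, normalized variants), `scale_factors`,
#'   `excitation_window_ms`, `ei_peak`, `ei_charge`, `n_sweeps`.
#' @export
decompose_cpsc <- function(sweeps, template, template_floor = 0.05,
                           charge_window_ms = 100, qc = TRUE,
                           per_sweep = FALSE) {
  stopifnot(inherits(template, "epsc_template"), length(sweeps) >= 1)
  if (qc) {
    contaminated <- vapply(sweeps, sweep_contaminated, logical(1))
    sweeps <- sweeps[!contaminated]
    if (length(sweeps) == 0) stop("decompose_cpsc: no clean sweeps")
  }
  if (length(sweeps) < 20 || length(sweeps) > 25)
    warning("decompose_cpsc: ", length(sweeps),
            " clean sweeps (20-25 recommended)")
  nv <- length(sweeps[[1]]$values)
  if (nv != length(template$waveform))
    stop("decompose_cpsc: sweeps and template differ in length")
  if (abs(sweeps[[1]]$dt - template$dt) > 1e-12)
    stop("decompose_cpsc: sweeps and template differ in dt")
  mat <- vapply(sweeps, sweep_baseline, numeric(nv))
  cpsc <- rowMeans(mat)
  t <- template$time_ms
  seg <- find_approximating_segment(cpsc, t)
  floor_pa <- template_floor * abs(template$peak_pa)
  usable <- seg[abs(template$waveform[seg]) >= floor_pa]
  if (!length(usable))
    stop("decompose_cpsc: all segment samples below the template floor")
  scales <- if (per_sweep) {
    sk <- vapply(seq_len(ncol(mat)), function(k)
      mean(mat[usable, k] / template$waveform[usable]), numeric(1))
    sk
  } else {
    cpsc[usable] / template$waveform[usable]
  }
  epsc <- mean(scales) * template$waveform
  ipsc <- cpsc - epsc
  epk <- min(epsc)          # inward peak, signed
  norm <- abs(epk)
  ew <- excitation_window(cpsc, t)
  ei_p <- ei_from_components(epsc, ipsc, t, charge_window_ms)
  structure(list(time_ms = t, cpsc = cpsc, epsc = epsc, ipsc = ipsc,
                 cpsc_norm = cpsc / norm, ipsc_norm = ipsc / norm,
                 epsc_norm = epsc / norm,
                 scale_factors = scales,
                 excitation_window_ms = ew$window_ms,
                 excitation_window_censored = ew$censored,
                 ei_peak = ei_p$ei_peak, ei_charge = ei_p$ei_charge,
                 epsc_peak_pa = epk, ipsc_peak_pa = max(ipsc),
                 n_sweeps = length(sweeps)),
            class = "cpsc_decomposition")
}

#' Excitation window of a compound PSC
#'
#' Duration of the excitatory (downward) component: from the first
#' departure below a noise floor after the stimulus to the first return to
#' baseline after the excitatory peak, linearly interpolated. The floor is
#' `floor_k` times the pre-stimulus SD, with a small relative guard for
#' noise-free input. A missing return crossing is right-censored at the
#' sweep end.
#'
#' @param waveform baseline-corrected cPSC waveform, pA.
#' @param time_ms time base, ms (stimulus at 0).
#' @param floor_k noise-floor multiplier.
#' @param rel_floor floor as a fraction of the excitatory peak depth, used
#'   when the baseline SD is (near) zero.
#' @return list with `window_ms` (NA with `defined = FALSE` when there is
#'   no departure) and `censored`.
#' @export
excitation_window <- function(waveform, time_ms, floor_k = 3,
                              rel_floor = 0.005) {
  pre <- waveform[time_ms < 0]
  post_i <- which(time_ms >= 0)
  depth <- -min(waveform[post_i])
  if (depth <= 0)
    return(list(window_ms = NA_real_, defined = FALSE, censored = FALSE))
  floor_pa <- max(floor_k * stats::sd(pre), rel_floor * depth)
  ip <- post_i[which.min(waveform[post_i])]
  dep <- post_i[post_i < ip]
  below <- dep[waveform[dep] < -floor_pa]
  if (!length(below))
    return(list(window_ms = NA_real_, defined = FALSE, censored = FALSE))
  i_start <- below[1]
  t_start <- if (i_start > 1)
    cross_time(time_ms, waveform, i_start - 1, -floor_pa)
  else time_ms[i_start]
  after <- which(time_ms > time_ms[ip])
  ret <- after[waveform[after] >= -floor_pa]
  if (!length(ret))
    return(list(window_ms = time_ms[length(time_ms)] - t_start,
                defined = TRUE, censored = TRUE))
  i_end <- ret[1]
  t_end <- cross_time(time_ms, waveform, i_end - 1, -floor_pa)
  list(window_ms = t_end - t_start, defined = TRUE, censored = FALSE)
}

# E/I by peak and by charge over [0, window] from component waveforms
ei_from_components <- function(epsc, ipsc, time_ms,
                               charge_window_ms = 100) {
  sel <- time_ms >= 0 & time_ms <= charge_window_ms
  trapz <- function(y, x) sum(diff(x) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  qe <- abs(trapz(epsc[sel], time_ms[sel]))
  qi <- abs(trapz(ipsc[sel], time_ms[sel]))
  pe <- abs(min(epsc)); pi_ <- abs(max(ipsc))
  list(ei_peak = if (pi_ > 0) pe / pi_ else NA_real_,
       ei_charge = if (qi > 0) qe / qi else NA_real_,
       epsc_charge = qe, ipsc_charge = qi)
}

#' E/I ratios from a decomposition result
#'
#' Peak basis: |EPSC peak| / |IPSC peak|. Charge basis: ratio of absolute
#' trapezoidal integrals over stimulus to stimulus + `charge_window_ms`.
#' The IPSC peak must exceed `ipsc_floor_pa` for the ratios to be reported
#' as bounded.
#'
#' @param result a `cpsc_decomposition`.
#' @param charge_window_ms integration window, ms.
#' @param ipsc_floor_pa noise floor for the IPSC peak, pA.
#' @return list with `ei_peak`, `ei_charge`, `bounded`.
#' @export
ei_from_decomposition <- function(result, charge_window_ms = 100,
                                  ipsc_floor_pa = 1) {
  stopifnot(inherits(result, "cpsc_decomposition"))
  e <- ei_from_components(result$epsc, result$ipsc, result$time_ms,
                          charge_window_ms)
  bounded <- result$ipsc_peak_pa > ipsc_floor_pa
  list(ei_peak = if (bounded) e$ei_peak else NA_real_,
       ei_charge = if (bounded) e$ei_charge else NA_real_,
       bounded = bounded)
}
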