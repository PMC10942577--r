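# Action-potential and passive-membrane feature extraction from
# current-clamp traces: AP detection, third-derivative voltage threshold,
# rheobase and rheobase charge transfer on ramps, waveform kinetics,
# excitability curves, input resistance, and interneuron firing-pattern
# classification.

# Savitzky-Golay smooth with a window of `width_ms` (odd sample count,
# minimum 5), polynomial order 3.
sg_smooth <- function(v, dt, width_ms = 0.5, order = 3) {
  n <- max(5L, as.integer(round(width_ms / dt)))
  if (n %% 2L == 0L) n <- n + 1L
  if (n >= length(v)) return(v)
  ord <- min(order, n - 2L)
  signal::sgolayfilt(v, p = ord, n = n)
}

#' Detect action potentials in a voltage trace
#'
#' An AP is an upward crossing of `cross_mv` whose ensuing peak reaches at
#' least `peak_min_mv`; peaks closer than `min_sep_ms` are merged to the
#' larger one. Each AP gets an analysis window from `pre_ms` before to
#' `post_ms` after its peak.
#'
#' @param x a voltage [trace].
#' @param cross_mv detection crossing level, mV.
#' @param peak_min_mv minimum peak potential, mV.
#' @param min_sep_ms minimum peak separation, ms.
#' @param pre_ms,post_ms analysis window around each peak, ms.
#' @return data frame with one row per AP: `start_idx`, `peak_idx`,
#'   `end_idx` (1-based sample indices), `peak_time_ms`, `peak_mv`. Zero
#'   rows when no APs.
#' @export
detect_aps <- function(x, cross_mv = -20, peak_min_mv = -10,
                       min_sep_ms = 2, pre_ms = 5, post_ms = 10) {
  stopifnot(inherits(x, "trace"), x$signal_kind == "voltage")
  v <- x$values
  n <- length(v)
  empty <- data.frame(start_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0), peak_time_ms = numeric(0),
                      peak_mv = numeric(0))
  up <- which(v[-n] < cross_mv & v[-1] >= cross_mv)
  if (length(up) == 0) return(empty)
  # peak of each suprathreshold excursion
  peaks <- integer(0)
  for (i in up) {
    j <- i + 1L
    below <- which(v[j:n] < cross_mv)
    end <- if (length(below)) j + below[1] - 2L else n
    seg <- j:end
    peaks <- c(peaks, seg[which.max(v[seg])])
  }
  # merge peaks closer than min_sep_ms, keeping the larger
  min_sep <- min_sep_ms / x$dt
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && (p - keep[length(keep)]) < min_sep) {
      if (v[p] > v[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  keep <- keep[v[keep] >= peak_min_mv]
  if (length(keep) == 0) return(empty)
  data.frame(start_idx = pmax(1L, keep - as.integer(round(pre_ms / x$dt))),
             peak_idx = keep,
             end_idx = pmin(n, keep + as.integer(round(post_ms / x$dt))),
             peak_time_ms = x$t0 + (keep - 1L) * x$dt,
             peak_mv = v[keep])
}

#' AP voltage threshold by the third-derivative criterion
#'
#' The threshold is the voltage at the first local maximum of d3V/dt3
#' preceding the AP peak, after Savitzky-Golay smoothing of the window. A
#' qualifying maximum must exceed `floor_k` times the robust noise floor of
#' d3V/dt3 in the early (baseline) part of the window and a small fraction
#' of the pre-peak d3V/dt3 maximum; if none qualifies the feature is
#' undetectable (`NA` with `ok = FALSE`).
#'
#' @param x a voltage [trace].
#' @param ap one row of [detect_aps] output (list or single-row data frame).
#' @param sg_width_ms smoothing window, ms.
#' @param floor_k noise-floor multiplier.
#' @param rel_floor minimum height relative to the pre-peak maximum of
#'   d3V/dt3.
#' @return list with `v_th` (mV), `t_th` (ms), `idx` (sample index) and
#'   `ok`.
#' @export
ap_threshold <- function(x, ap, sg_width_ms = 0.5, floor_k = 5,
                         rel_floor = 0.05) {
  stopifnot(inherits(x, "trace"))
  i1 <- ap$start_idx[1]; ip <- ap$peak_idx[1]; i2 <- ap$end_idx[1]
  bad <- list(v_th = NA_real_, t_th = NA_real_, idx = NA_integer_,
              ok = FALSE)
  if (ip - i1 < 8) return(bad)
  seg <- i1:i2
  vs <- sg_smooth(x$values[seg], x$dt, sg_width_ms)
  d3 <- diff(vs, differences = 3) / x$dt^3
  # index k of d3 sits between samples k+1 and k+2 of the segment; attribute
  # it to sample k + 2 (half-sample bias is far below the tolerance of use)
  off <- 2L
  pk_local <- ip - i1 + 1L
  upto <- pk_local - off
  if (upto < 3) return(bad)
  d3pre <- d3[seq_len(min(upto, length(d3)))]
  nb <- max(3L, as.integer(floor(0.3 * length(d3pre))))
  floor_est <- floor_k * stats::mad(d3pre[seq_len(nb)], center = 0)
  hmin <- max(floor_est, rel_floor * max(d3pre), .Machine$double.eps)
  k <- seq(2, length(d3pre) - 1)
  is_max <- d3pre[k] > d3pre[k - 1] & d3pre[k] >= d3pre[k + 1] &
    d3pre[k] > hmin
  if (!any(is_max)) return(bad)
  k_th <- k[which(is_max)[1]]
  idx <- i1 + (k_th + off) - 1L
  list(v_th = vs[k_th + off], t_th = x$t0 + (idx - 1L) * x$dt, idx = idx,
       ok = TRUE)
}

#' Rheobase and rheobase charge transfer from a ramp protocol
#'
#' Rheobase is the injected ramp current at the threshold time of the first
#' AP; charge transfer is the time-integral of injected current
#' (trapezoidal) from the start of the depolarizing segment -- the point
#' where the ramp crosses 0 pA when it has a hyperpolarizing onset -- to
#' the threshold time. 1 pA.s = 1 pC.
#'
#' @param protocol a ramp [protocol_spec] (pA/ms).
#' @param t_th threshold time of the first AP, ms.
#' @return list with `rheobase_pa` and `charge_pc`.
#' @export
rheobase_and_charge <- function(protocol, t_th) {
  stopifnot(inherits(protocol, "protocol_spec"), protocol$kind == "ramp")
  if (t_th < protocol$ramp_onset)
    stop("rheobase_and_charge: threshold time precedes ramp onset")
  rate <- protocol$ramp_rate
  pre <- protocol$ramp_pre_offset
  rheo <- pre + rate * (t_th - protocol$ramp_onset)
  t_zero <- if (pre < 0) protocol$ramp_onset - pre / rate else
    protocol$ramp_onset
  if (t_th <= t_zero) return(list(rheobase_pa = rheo, charge_pc = 0))
  # trapezoid on the linear segment [t_zero, t_th]; exact for a ramp
  i_zero <- max(0, pre + rate * (t_zero - protocol$ramp_onset))
  charge <- 0.5 * (i_zero + rheo) * (t_th - t_zero) / 1000
  list(rheobase_pa = rheo, charge_pc = charge)
}

# interpolated crossing time of `level` between samples i and i+1
cross_time <- function(t, v, i, level) {
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Waveform features of a single AP
#'
#' Amplitude is threshold-to-peak; rise/fall times span 10-90% of that
#' amplitude on the upstroke/downstroke (linear interpolation between
#' samples); duration is the interval between the upward and downward
#' -10 mV crossings; maximum rise rate is the peak of the smoothed first
#' derivative on the upstroke.
#'
#' @param x a voltage [trace].
#' @param ap one row of [detect_aps] output.
#' @param v_th threshold voltage from [ap_threshold], mV.
#' @param t_th threshold time, ms.
#' @param duration_level_mv level for the duration measurement, mV.
#' @return list with `peak_mv`, `amplitude_mv`, `max_rise_mvms`,
#'   `rise_ms`, `fall_ms`, `duration_ms` (NA when the peak stays below the
#'   duration level).
#' @export
ap_waveform_features <- function(x, ap, v_th, t_th,
                                 duration_level_mv = -10) {
  stopifnot(inherits(x, "trace"))
  seg <- ap$start_idx[1]:ap$end_idx[1]
  v <- x$values[seg]
  t <- x$t0 + (seg - 1) * x$dt
  ip <- ap$peak_idx[1] - ap$start_idx[1] + 1L
  peak <- v[ip]
  amp <- peak - v_th
  i_th <- max(1L, which.min(abs(t - t_th)))
  # max rise rate on the upstroke (threshold -> peak): raw first
  # difference with a short boxcar (positive kernel, so linear segments
  # are never overshot)
  up <- i_th:ip
  dv <- run_mean(diff(v) / x$dt, max(1L, as.integer(round(0.1 / x$dt))))
  max_rise <- if (length(up) > 1) max(dv[up[-length(up)]]) else NA_real_
  lvl10 <- v_th + 0.1 * amp
  lvl90 <- v_th + 0.9 * amp
  first_up_cross <- function(level, from, to) {
    ii <- from:(to - 1)
    hit <- ii[v[ii] < level & v[ii + 1] >= level]
    if (length(hit)) cross_time(t, v, hit[1], level) else NA_real_
  }
  first_down_cross <- function(level, from, to) {
    if (from >= to) return(NA_real_)
    ii <- from:(to - 1)
    hit <- ii[v[ii] >= level & v[ii + 1] < level]
    if (length(hit)) cross_time(t, v, hit[1], level) else NA_real_
  }
  t10u <- first_up_cross(lvl10, i_th, ip)
  t90u <- first_up_cross(lvl90, i_th, ip)
  t90d <- first_down_cross(lvl90, ip, length(v))
  t10d <- first_down_cross(lvl10, ip, length(v))
  dur <- NA_real_
  if (peak > duration_level_mv) {
    tu <- first_up_cross(duration_level_mv, 1L, ip)
    td <- first_down_cross(duration_level_mv, ip, length(v))
    if (!is.na(tu) && !is.na(td)) dur <- td - tu
  }
  list(peak_mv = peak, amplitude_mv = amp, max_rise_mvms = max_rise,
       rise_ms = t90u - t10u, fall_ms = t10d - t90d, duration_ms = dur)
}

#' Full AP feature set for one trace
#'
#' Runs detection, thresholding and waveform measurement on every AP;
#' rheobase and charge are reported (from the first AP) when the protocol
#' is a ramp.
#'
#' @param x a voltage [trace].
#' @param protocol optional [protocol_spec]; defaults to the trace's own.
#' @param ... passed to [detect_aps].
#' @return list with `per_ap` (data frame, one row per AP) and `summary`
#'   (list: `n_ap`, `rheobase_pa`, `charge_pc`).
#' @export
ap_feature_set <- function(x, protocol = x$protocol, ...) {
  aps <- detect_aps(x, ...)
  rows <- lapply(seq_len(nrow(aps)), function(i) {
    ap <- aps[i, ]
    th <- ap_threshold(x, ap)
    wf <- if (th$ok) ap_waveform_features(x, ap, th$v_th, th$t_th)
    else list(peak_mv = ap$peak_mv, amplitude_mv = NA_real_,
              max_rise_mvms = NA_real_, rise_ms = NA_real_,
              fall_ms = NA_real_, duration_ms = NA_real_)
    data.frame(ap = i, t_peak_ms = ap$peak_time_ms, v_th_mv = th$v_th,
               t_th_ms = th$t_th, threshold_ok = th$ok,
               peak_mv = wf$peak_mv, amplitude_mv = wf$amplitude_mv,
               max_rise_mvms = wf$max_rise_mvms, rise_ms = wf$rise_ms,
               fall_ms = wf$fall_ms, duration_ms = wf$duration_ms)
  })
  per_ap <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ap = integer(0))
  summ <- list(n_ap = nrow(aps), rheobase_pa = NA_real_,
               charge_pc = NA_real_)
  if (!is.null(protocol) && protocol$kind == "ramp" && nrow(aps) > 0 &&
      isTRUE(per_ap$threshold_ok[1]) && !is.na(per_ap$t_th_ms[1])) {
    rc <- rheobase_and_charge(protocol, per_ap$t_th_ms[1])
    summ$rheobase_pa <- rc$rheobase_pa
    summ$charge_pc <- rc$charge_pc
  }
  list(per_ap = per_ap, summary = summ)
}

#' Mean AP count per set membrane potential
#'
#' For the excitability protocol in which the membrane potential is set to
#' each level (e.g. -64 to -55 mV) and spontaneous APs are counted over a
#' fixed period, with several trials per level.
#'
#' @param traces list of voltage [trace]s (one per trial).
#' @param potentials numeric vector, set potential (mV) for each trace.
#' @param ... passed to [detect_aps].
#' @return data frame ordered by potential: `potential_mv`, `mean_count`,
#'   `n_trials`, plus a `gaps` attribute listing missing 1 mV levels within
#'   the spanned range.
#' @export
excitability_curve <- function(traces, potentials, ...) {
  stopifnot(length(traces) == length(potentials))
  counts <- vapply(traces, function(tr) nrow(detect_aps(tr, ...)),
                   numeric(1))
  lev <- sort(unique(potentials))
  out <- data.frame(
    potential_mv = lev,
    mean_count = vapply(lev, function(p) mean(counts[potentials == p]),
                        numeric(1)),
    n_trials = vapply(lev, function(p) sum(potentials == p), numeric(1)))
  expected <- seq(min(lev), max(lev), by = 1)
  attr(out, "gaps") <- setdiff(expected, lev)
  out
}

#' Passive properties from a current-step response
#'
#' Input resistance is `|dV / dI|` with `dV` the difference between the
#' mean over the last `settle_ms` of the step and the mean over the
#' `baseline_ms` preceding the step.
#'
#' @param x a voltage [trace].
#' @param protocol a step [protocol_spec]; defaults to the trace's own.
#' @param baseline_ms,settle_ms averaging windows, ms.
#' @return list with `r_in_mohm`, `rmp_mv` (the pre-step baseline mean),
#'   `delta_v_mv`, `step_pa`, `measurement_potential_mv`.
#' @export
passive_props <- function(x, protocol = x$protocol, baseline_ms = 100,
                          settle_ms = 100) {
  stopifnot(inherits(x, "trace"), x$signal_kind == "voltage",
            inherits(protocol, "protocol_spec"), protocol$kind == "step")
  if (protocol$step_duration < 300)
    stop("passive_props: step shorter than 300 ms; response not settled")
  t <- trace_times(x)
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  if (on - x$t0 < baseline_ms)
    stop("passive_props: need >= ", baseline_ms, " ms pre-step baseline")
  base <- mean(x$values[t >= on - baseline_ms & t < on])
  plateau <- mean(x$values[t >= off - settle_ms & t < off])
  dv <- plateau - base
  list(r_in_mohm = abs(dv / protocol$step_amplitude) * 1000,
       rmp_mv = base, delta_v_mv = dv,
       step_pa = protocol$step_amplitude,
       measurement_potential_mv = base)
}

#' Classify an interneuron firing pattern
#'
#' From the response to a depolarizing step (100 pA / 600 ms in the
#' standard protocol): stuttering-like when the ISI coefficient of
#' variation exceeds `cv_stutter`; otherwise fast-spiking when the maximum
#' instantaneous rate reaches `fast_hz` and the adaptation index (last ISI
#' over first ISI) stays below `adapt_max`; otherwise regular-spiking.
#'
#' @param x a voltage [trace].
#' @param cv_stutter,fast_hz,adapt_max decision thresholds.
#' @param ... passed to [detect_aps].
#' @return list with `label` (one of `"fast_spiking"`, `"regular_spiking"`,
#'   `"stuttering_like"`, `"undetermined"`) and `metrics` (max
#'   instantaneous rate Hz, adaptation index, ISI CV; NA when < 3 APs).
#' @export
classify_firing_pattern <- function(x, cv_stutter = 0.5, fast_hz = 50,
                                    adapt_max = 1.3, ...) {
  aps <- detect_aps(x, ...)
  if (nrow(aps) < 3)
    return(list(label = "undetermined",
                metrics = list(max_rate_hz = NA_real_,
                               adaptation = NA_real_, isi_cv = NA_real_)))
  isi <- diff(aps$peak_time_ms)
  metrics <- list(max_rate_hz = 1000 / min(isi),
                  adaptation = isi[length(isi)] / isi[1],
                  isi_cv = stats::sd(isi) / mean(isi))
  label <- if (metrics$isi_cv > cv_stutter) "stuttering_like"
  else if (metrics$max_rate_hz >= fast_hz &&
           metrics$adaptation < adapt_max) "fast_spiking"
  else "regular_spiking"
  list(label = label, metrics = metrics)
}
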