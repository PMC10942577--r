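# Spontaneous/miniature PSC event detection and statistics: threshold
# detection on a rolling-median baseline, instantaneous frequencies,
# per-cell-normalized frequency distributions, cumulative probabilities,
# rates, E/I ratios and drug-normalized frequency time courses.

#' Detect PSC events in a voltage-clamp current trace
#'
#' The trace is baseline-corrected by subtracting a rolling median
#' (`baseline_ms` window); an event is an excursion beyond `threshold_pa`
#' in the declared polarity, placed at its local extremum, with amplitude
#' measured from the local baseline. Extrema closer than `refractory_ms`
#' are merged to the larger one. Excursions containing several
#' sub-threshold-separated peaks are kept but QC-flagged as overlapping
#' rather than removed.
#'
#' @param x a current [trace].
#' @param polarity `"inward"` (events go negative) or `"outward"`.
#' @param threshold_pa detection threshold, pA (10 pA is the standard
#'   setting for sEPSC/sIPSC analysis).
#' @param refractory_ms merge window, ms.
#' @param baseline_ms rolling-median window, ms.
#' @return object of class `event_list`: list with `events` (data frame:
#'   `time_ms`, `amplitude_pa` signed, `inst_freq_hz` -- NA for the first
#'   event, `overlap` flag), `threshold_pa`, `polarity`, `duration_s`.
#' @export
detect_events <- function(x, polarity = c("inward", "outward"),
                          threshold_pa = 10, refractory_ms = 2,
                          baseline_ms = 200) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(x, "trace"), x$signal_kind == "current")
  v <- x$values
  k <- as.integer(round(baseline_ms / x$dt))
  if (k %% 2L == 0L) k <- k + 1L
  base <- if (k >= 3 && k < length(v)) stats::runmed(v, k, endrule = "median")
  else rep(stats::median(v), length(v))
  w <- v - base
  if (polarity == "inward") w <- -w  # analyze positive excursions
  n <- length(w)
  # light smoothing (0.5 ms) for peak finding; amplitudes read from raw w
  ws <- run_mean(w, max(1L, as.integer(round(0.5 / x$dt))))
  above <- ws > threshold_pa
  if (!any(above)) {
    ev <- data.frame(time_ms = numeric(0), amplitude_pa = numeric(0),
                     inst_freq_hz = numeric(0), overlap = logical(0))
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    reg <- cbind(starts[r$values], ends[r$values])
    peaks <- integer(0); overlap <- logical(0)
    ref_n <- max(1L, as.integer(round(refractory_ms / x$dt)))
    cand <- integer(0); cand_multi <- logical(0)
    for (i in seq_len(nrow(reg))) {
      seg <- reg[i, 1]:reg[i, 2]
      wseg <- ws[seg]
      locmax <- seg[which(diff(sign(diff(c(-Inf, wseg, -Inf)))) == -2)]
      if (!length(locmax)) locmax <- seg[which.max(wseg)]
      cand <- c(cand, locmax)
      cand_multi <- c(cand_multi, rep(length(locmax) > 1, length(locmax)))
    }
    # a candidate counts only if it rises by >= threshold above the trough
    # since the previously kept peak (prominence), so noise wiggles on a
    # decay tail -- inside or after an excursion -- do not register
    last_kept <- NA_integer_
    for (j in seq_along(cand)) {
      p <- cand[j]
      trough <- if (is.na(last_kept)) 0 else min(ws[last_kept:p])
      if (ws[p] - trough >= threshold_pa) {
        peaks <- c(peaks, p)
        overlap <- c(overlap, cand_multi[j])
        last_kept <- p
      }
    }
    # merge peaks closer than refractory_ms, keep the larger extremum
    keep_i <- integer(0); keep_ov <- logical(0)
    for (j in seq_along(peaks)) {
      p <- peaks[j]
      if (length(keep_i) && (p - keep_i[length(keep_i)]) < ref_n) {
        ki <- length(keep_i)
        keep_ov[ki] <- TRUE
        if (ws[p] > ws[keep_i[ki]]) keep_i[ki] <- p
      } else {
        keep_i <- c(keep_i, p); keep_ov <- c(keep_ov, overlap[j])
      }
    }
    # refine peak position on the raw trace (+/- 0.3 ms) and measure the
    # amplitude against the local pre-event baseline (median over
    # [-10, -2] ms); corrected amplitudes below threshold drop out
    half <- max(1L, as.integer(round(0.3 / x$dt)))
    keep_i <- vapply(keep_i, function(p) {
      j <- max(1L, p - half):min(n, p + half)
      j[which.max(w[j])]
    }, integer(1))
    lead <- as.integer(round(2 / x$dt))
    back <- as.integer(round(10 / x$dt))
    loc_amp <- vapply(keep_i, function(p) {
      j <- max(1L, p - back):max(1L, p - lead)
      w[p] - stats::median(w[j])
    }, numeric(1))
    ok <- loc_amp >= threshold_pa
    keep_i <- keep_i[ok]; keep_ov <- keep_ov[ok]; loc_amp <- loc_amp[ok]
    amp <- loc_amp * (if (polarity == "inward") -1 else 1)
    tms <- x$t0 + (keep_i - 1) * x$dt
    inst <- if (length(tms)) c(NA_real_, 1000 / diff(tms)) else numeric(0)
    ev <- data.frame(time_ms = tms, amplitude_pa = amp,
                     inst_freq_hz = inst, overlap = keep_ov)
  }
  structure(list(events = ev, threshold_pa = threshold_pa,
                 polarity = polarity,
                 duration_s = length(v) * x$dt / 1000),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list: %d %s events in %.3g s (threshold %g pA)>\n",
              nrow(x$events), x$polarity, x$duration_s, x$threshold_pa))
  invisible(x)
}

#' Instantaneous event frequencies
#'
#' `f_i = 1000 / (t_i - t_{i-1})` Hz, assigned to the later event of each
#' pair; an event list with fewer than two events yields an empty vector.
#'
#' @param x an `event_list` from [detect_events], or a numeric vector of
#'   event times in ms.
#' @return numeric vector of frequencies, Hz (length `n_events - 1`).
#' @export
instantaneous_frequencies <- function(x) {
  times <- if (inherits(x, "event_list")) x$events$time_ms else
    as.numeric(x)
  if (length(times) < 2) return(numeric(0))
  1000 / diff(times)
}

#' Pooled per-cell-normalized frequency distribution
#'
#' Histogram of instantaneous frequencies pooled over cells, with per-bin
#' counts divided by the number of cells, so that the sum of normalized
#' counts times `n_cells` equals the pooled event-pair count exactly.
#'
#' @param cell_events list of `event_list` objects (one per cell).
#' @param bin_hz bin width, Hz.
#' @param trace_s nominal trace length per cell, s; cells whose recorded
#'   duration differs get a warning flag (still computed).
#' @return list of class `freq_distribution`: `bin_edges_hz`,
#'   `counts_per_cell`, `n_cells`, `n_pooled`, `mixed_lengths` flag.
#' @export
frequency_distribution <- function(cell_events, bin_hz = 2, trace_s = 30) {
  stopifnot(length(cell_events) >= 1)
  freqs <- unlist(lapply(cell_events, instantaneous_frequencies))
  n_cells <- length(cell_events)
  mixed <- any(vapply(cell_events, function(e)
    abs(e$duration_s - trace_s) > 1e-6, logical(1)))
  top <- if (length(freqs)) max(freqs) else bin_hz
  edges <- seq(0, bin_hz * ceiling(top / bin_hz + 1e-12), by = bin_hz)
  if (length(edges) < 2) edges <- c(0, bin_hz)
  counts <- if (length(freqs))
    graphics::hist(freqs, breaks = edges, plot = FALSE,
                   right = FALSE)$counts
  else rep(0L, length(edges) - 1)
  structure(list(bin_edges_hz = edges, counts_per_cell = counts / n_cells,
                 n_cells = n_cells, n_pooled = length(freqs),
                 trace_s = trace_s, mixed_lengths = mixed),
            class = "freq_distribution")
}

#' Empirical cumulative probability of a sample
#'
#' Right-continuous ECDF evaluated at the sorted unique values; the final
#' cumulative fraction is exactly 1.
#'
#' @param values numeric vector (>= 1 value).
#' @return data frame with `value` and `cum_prob`.
#' @export
cumulative_probability <- function(values) {
  if (length(values) == 0)
    stop("cumulative_probability: empty input")
  v <- sort(unique(values))
  data.frame(value = v, cum_prob = stats::ecdf(values)(v))
}

#' Event rate of an event list
#' @param x an `event_list`.
#' @return list with `per_min` and `hz`.
#' @export
event_rate <- function(x) {
  stopifnot(inherits(x, "event_list"), x$duration_s > 0)
  n <- nrow(x$events)
  list(per_min = n / (x$duration_s / 60), hz = n / x$duration_s)
}

#' Excitation/inhibition ratio
#'
#' @param exc,inh excitatory and inhibitory measures on a common basis
#'   (mean event rate, peak amplitude magnitude, or charge magnitude).
#' @param basis label: `"frequency"`, `"peak"` or `"charge"`.
#' @return list of class `ei_ratio`: `exc`, `inh`, `ratio` (NA with
#'   `defined = FALSE` when `inh` is 0), `basis`.
#' @export
ei_ratio <- function(exc, inh, basis = c("frequency", "peak", "charge")) {
  basis <- match.arg(basis)
  defined <- is.finite(inh) && inh > 0
  structure(list(exc = exc, inh = inh,
                 ratio = if (defined) exc / inh else NA_real_,
                 defined = defined, basis = basis),
            class = "ei_ratio")
}

#' Drug-normalized frequency time course
#'
#' Event rate in the drug window expressed as percent of the rate in the
#' baseline window ("normalized frequency").
#'
#' @param x an `event_list`.
#' @param baseline_window,drug_window length-2 numeric windows in ms,
#'   non-overlapping.
#' @return list with `percent_of_basal`, the two window rates (per min),
#'   and `defined` (FALSE when the baseline rate is zero).
#' @export
normalized_frequency_timecourse <- function(x, baseline_window,
                                            drug_window) {
  stopifnot(inherits(x, "event_list"),
            length(baseline_window) == 2, length(drug_window) == 2)
  bw <- sort(baseline_window); dw <- sort(drug_window)
  if (max(bw[1], dw[1]) < min(bw[2], dw[2]))
    stop("normalized_frequency_timecourse: windows overlap")
  rate_in <- function(w) {
    n <- sum(x$events$time_ms >= w[1] & x$events$time_ms < w[2])
    n / ((w[2] - w[1]) / 60000)
  }
  rb <- rate_in(bw); rd <- rate_in(dw)
  if (rb <= 0)
    return(list(percent_of_basal = NA_real_, baseline_per_min = rb,
                drug_per_min = rd, defined = FALSE))
  list(percent_of_basal = 100 * rd / rb, baseline_per_min = rb,
       drug_per_min = rd, defined = TRUE)
}
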