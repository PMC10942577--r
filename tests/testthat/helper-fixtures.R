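# Shared fixture builders: everything is generated in code at test time.

# voltage trace with stereotyped APs at given times (ms) on a flat baseline
spike_train_trace <- function(times_ms, duration_ms = NULL, dt = 0.1,
                              baseline = -70, amp = 105) {
  if (is.null(duration_ms)) duration_ms <- max(times_ms) + 20
  t <- seq(0, duration_ms, by = dt)
  v <- rep(baseline, length(t))
  for (st in times_ms) v <- v + amp * dentephys:::ap_waveform(t - st)
  trace(v, dt = dt, signal_kind = "voltage")
}

# greedy one-to-one matching of detected event times to truth within tol
match_events <- function(detected, truth, tol_ms = 2) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (tt in detected) {
    d <- abs(truth - tt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_ms) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp,
       recall = tp / max(1L, length(truth)),
       precision = tp / max(1L, length(detected)))
}

trapz <- function(y, x) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# passive membrane parameter set (spike and rectifier conductances absent)
passive_params <- function(..., g_kv7_max = 0) {
  p <- membrane_params(g_kv7_max = g_kv7_max, ...)
  p$g_na <- 0
  p$g_kd <- 0
  p
}
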