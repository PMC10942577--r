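# Kv7 (M-current) analysis by condition subtraction: XE991-sensitive
# current from paired voltage-clamp ramps, quasi-steady-state I-V curves
# normalized to capacitance, holding-current and membrane-potential shifts,
# and input-resistance changes.

#' Subtract a treated trace from a basal trace
#'
#' Sample-wise `basal - treated`, so the drug-sensitive (e.g. Kv7) current
#' is positive-outward. Traces must share dt and length (trial-averaged
#' inputs are accepted).
#'
#' @param basal,treated current or voltage [trace]s.
#' @return a [trace] of the difference, condition `"difference"`.
#' @export
subtract_conditions <- function(basal, treated) {
  stopifnot(inherits(basal, "trace"), inherits(treated, "trace"))
  if (length(basal$values) != length(treated$values))
    stop("subtract_conditions: traces differ in length")
  if (abs(basal$dt - treated$dt) > 1e-12)
    stop("subtract_conditions: traces differ in dt")
  trace(basal$values - treated$values, dt = basal$dt, t0 = basal$t0,
        signal_kind = basal$signal_kind, condition = "difference",
        cell_id = basal$cell_id, genotype = basal$genotype,
        protocol = basal$protocol)
}

#' Quasi-steady-state I-V curve from a ramp-evoked current
#'
#' At each target command voltage (every `step_mv` from the ramp start to
#' its end by default), the current is averaged over command samples within
#' `window_mv / 2` of the target and divided by the cell capacitance.
#'
#' @param current a current [trace] (e.g. the XE991-sensitive difference).
#' @param command the voltage-command [trace] of the ramp (same time base).
#' @param capacitance_pf cell capacitance, pF (> 0).
#' @param step_mv spacing of sampled voltages, mV.
#' @param window_mv averaging window around each target, mV.
#' @param from_mv,to_mv first and last target voltage; default -95 to +5.
#' @return object of class `iv_curve`: data frame `curve` with
#'   `voltage_mv`, `density_pa_pf`, `current_pa`, `n_samples`, plus
#'   `capacitance_pf` and `dropped` (targets outside the ramp range).
#' @export
build_iv_curve <- function(current, command, capacitance_pf, step_mv = 5,
                           window_mv = 0.01, from_mv = -95, to_mv = 5) {
  stopifnot(inherits(current, "trace"), inherits(command, "trace"),
            capacitance_pf > 0)
  if (length(current$values) != length(command$values))
    stop("build_iv_curve: current and command differ in length")
  v <- command$values
  if (any(diff(v) < -1e-12) && any(diff(v) > 1e-12))
    stop("build_iv_curve: voltage command is not monotone")
  targets <- seq(from_mv, to_mv, by = step_mv)
  lo <- min(v); hi <- max(v)
  dropped <- targets[targets < lo - window_mv / 2 |
                       targets > hi + window_mv / 2]
  targets <- setdiff(targets, dropped)
  rows <- lapply(targets, function(vt) {
    sel <- abs(v - vt) <= window_mv / 2
    if (!any(sel)) {
      # window narrower than the voltage step between samples: nearest sample
      sel <- which.min(abs(v - vt))
    }
    i_mean <- mean(current$values[sel])
    data.frame(voltage_mv = vt, density_pa_pf = i_mean / capacitance_pf,
               current_pa = i_mean, n_samples = sum(sel))
  })
  structure(list(curve = do.call(rbind, rows),
                 capacitance_pf = capacitance_pf, dropped = dropped),
            class = "iv_curve")
}

# mean over a stationary segment with a linear-drift check
segment_mean <- function(x, drift_tol = 0.10) {
  t_min <- trace_times(x) / 60000
  fit <- stats::lm.fit(cbind(1, t_min), x$values)
  m <- mean(x$values)
  drift <- abs(fit$coefficients[2])
  flag <- is.finite(drift) && abs(m) > 0 && drift > drift_tol * abs(m)
  list(mean = m, drift_flag = flag)
}

#' Holding-current shift between conditions
#'
#' Difference of segment means (`treated - basal`) of the holding current
#' at a fixed potential; Kv7 block removes a standing outward current, so
#' the expected delta is negative.
#'
#' @param basal,treated current [trace]s of stationary holding segments
#'   (>= `min_s` seconds each).
#' @param min_s minimum segment duration, s.
#' @return list of class `condition_delta`: `quantity`, `basal`, `treated`,
#'   `delta`, `percent` (NA when basal is 0), `drift_flag`.
#' @export
holding_shift <- function(basal, treated, min_s = 10) {
  stopifnot(inherits(basal, "trace"), inherits(treated, "trace"))
  for (tr in list(basal, treated))
    if (length(tr$values) * tr$dt / 1000 < min_s)
      stop("holding_shift: segment shorter than ", min_s, " s")
  b <- segment_mean(basal); d <- segment_mean(treated)
  delta <- d$mean - b$mean
  structure(list(quantity = "holding_current_pa", basal = b$mean,
                 treated = d$mean, delta = delta,
                 percent = if (b$mean != 0) 100 * delta / b$mean else
                   NA_real_,
                 drift_flag = b$drift_flag || d$drift_flag),
            class = "condition_delta")
}

#' Membrane-potential shift between conditions
#'
#' As [holding_shift] but on voltage traces with the potential initially
#' set to a fixed level; Kv7 block depolarizes, so the expected delta is
#' positive.
#'
#' @inheritParams holding_shift
#' @return a `condition_delta` with quantity `membrane_potential_mv`.
#' @export
vm_shift <- function(basal, treated, min_s = 10) {
  out <- holding_shift(basal, treated, min_s = min_s)
  out$quantity <- "membrane_potential_mv"
  out
}

#' Input-resistance change between conditions
#'
#' @param basal_rin,treated_rin input resistances (MOhm) from
#'   [passive_props] at the same potential.
#' @return a `condition_delta` with quantity `input_resistance_mohm` and
#'   `percent` the percent increase.
#' @export
rin_change <- function(basal_rin, treated_rin) {
  if (!is.finite(basal_rin) || basal_rin <= 0)
    stop("rin_change: basal input resistance must be > 0")
  structure(list(quantity = "input_resistance_mohm", basal = basal_rin,
                 treated = treated_rin, delta = treated_rin - basal_rin,
                 percent = 100 * (treated_rin - basal_rin) / basal_rin,
                 drift_flag = FALSE),
            class = "condition_delta")
}

#' @export
print.condition_delta <- function(x, ...) {
  cat(sprintf("<condition_delta %s: basal %.4g, treated %.4g, delta %.4g (%s%%)>\n",
              x$quantity, x$basal, x$treated, x$delta,
              if (is.na(x$percent)) "NA" else sprintf("%.3g", x$percent)))
  invisible(x)
}
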