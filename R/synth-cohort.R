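# Synthetic WT/KO cohort: per-cell parameter jitter around group means,
# every requested protocol simulated per cell with ground truth retained.
# The KO group differs mechanistically only by its larger Kv7 conductance;
# synaptic-input and suppression settings encode the circuit-level
# consequences measured downstream.

#' Default cohort study settings
#'
#' Event rates are Hz of spontaneous PSCs onto the recorded cell type
#' (excitatory drive onto interneurons is reduced in KO); `suppression` is
#' the gamma-burst suppression factor per genotype; `ipsc_peak_pa` the
#' evoked IPSC component per genotype (weaker inhibition in KO).
#'
#' @return named list of cohort settings.
#' @export
cohort_settings <- function() {
  list(event_rates = list(WT = c(exc = 10, inh = 5),
                          KO = c(exc = 7, inh = 5)),
       rate_cv = 0.1,
       suppression = c(WT = 0.3, KO = 0.7),
       p_base = 0.5, n_tg_trials = 20,
       ipsc_peak_pa = c(WT = 80, KO = 50), epsc_peak_pa = -120,
       n_ramp_trials = 4,
       ramp = list(rate = 0.15, onset = 100, pre_offset = -50,
                   depol_ms = 2000),
       vc_ramp = list(rate = 0.02, from = -95, to = 5),
       rin_step_pa = 60, rin_potential = -45,
       noise_sigma = 5, dt_ramp = 0.02, dt_vc = 0.05)
}

# lognormal multiplicative jitter with coefficient of variation cv
jitter_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

# per-cell parameter set: conductances and capacitance jittered
jitter_params <- function(params, cv, seed) {
  withr::with_seed(seed, {
    f <- jitter_factor(5, cv)
    params$C <- params$C * f[1]
    params$g_leak <- params$g_leak * f[2]
    params$g_kv7_max <- params$g_kv7_max * f[3]
    params$g_na <- params$g_na * f[4]
    params$g_kd <- params$g_kd * f[5]
    params
  })
}

# passive variant: Na+ and fast K+ channels blocked (TTX / Cd2+ recordings)
passive_variant <- function(params, kv7_blocked = FALSE) {
  params$g_na <- 0
  params$g_kd <- 0
  if (kv7_blocked) params$g_kv7_max <- 0
  params
}

#' Generate a synthetic WT/KO cohort
#'
#' Each cell gets parameters jittered around its group means (lognormal,
#' CV `jitter_cv`) and every requested protocol simulated with ground
#' truth. Fully reproducible from `seed`.
#'
#' @param n_per_group cells per genotype (>= 1).
#' @param wt_params,ko_pars group-mean [membrane_params]; the KO profile
#'   defaults to WT with `g_kv7_max` scaled by 1.5.
#' @param protocols subset of `c("ramp", "rin45", "vc_ramp", "events",
#'   "theta_gamma", "cpsc")`.
#' @param jitter_cv per-cell parameter CV.
#' @param seed master seed.
#' @param settings study settings, see [cohort_settings].
#' @return object of class `cohort`: list of `cells`, each with `cell_id`,
#'   `genotype`, `params`, `record` (a [cell_record]) and one entry per
#'   simulated protocol holding traces and truth.
#' @export
make_cohort <- function(n_per_group = 15,
                        wt_params = membrane_params(genotype = "WT"),
                        ko_pars = ko_params(wt_params),
                        protocols = c("ramp", "rin45", "vc_ramp", "events",
                                      "theta_gamma"),
                        jitter_cv = 0.1, seed = 1,
                        settings = cohort_settings()) {
  stopifnot(n_per_group >= 1)
  protocols <- match.arg(protocols,
                         c("ramp", "rin45", "vc_ramp", "events",
                           "theta_gamma", "cpsc"), several.ok = TRUE)
  n_cells <- 2 * n_per_group
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1, n_cells * 8))
  seed_at <- function(cell, slot) seeds[(cell - 1) * 8 + slot]
  s <- settings
  cells <- lapply(seq_len(n_cells), function(ci) {
    genotype <- if (ci <= n_per_group) "WT" else "KO"
    base <- if (genotype == "WT") wt_params else ko_pars
    params <- jitter_params(base, jitter_cv, seed_at(ci, 1))
    params$noise_sigma <- s$noise_sigma
    cell_id <- sprintf("%s_%02d", tolower(genotype),
                       if (genotype == "WT") ci else ci - n_per_group)
    cell <- list(cell_id = cell_id, genotype = genotype, params = params)

    if ("ramp" %in% protocols) {
      ramp <- protocol_spec("ramp", ramp_rate = s$ramp$rate,
                            ramp_onset = s$ramp$onset,
                            ramp_pre_offset = s$ramp$pre_offset)
      t_zero <- s$ramp$onset - s$ramp$pre_offset / s$ramp$rate
      dur <- t_zero + s$ramp$depol_ms
      trials <- lapply(seq_len(s$n_ramp_trials), function(k)
        simulate_membrane(params, ramp, dur, dt = s$dt_ramp,
                          seed = seed_at(ci, 2) + k, cell_id = cell_id))
      cell$ramp <- list(trials = trials, protocol = ramp, t_zero = t_zero,
                        count_window = c(t_zero, t_zero + s$ramp$depol_ms))
    }
    if ("rin45" %in% protocols) {
      step <- protocol_spec("step", step_amplitude = s$rin_step_pa,
                            step_onset = 200, step_duration = 500,
                            holding_potential = s$rin_potential)
      run_rin <- function(kv7_blocked, slot) {
        p <- passive_variant(params, kv7_blocked)
        hold <- holding_current_for(p, s$rin_potential)
        simulate_membrane(p, step, 800, dt = s$dt_ramp,
                          seed = seed_at(ci, slot),
                          holding_current = hold, cell_id = cell_id,
                          condition = if (kv7_blocked) "XE991" else "basal")
      }
      cell$rin45 <- list(basal = run_rin(FALSE, 3), xe991 = run_rin(TRUE, 4),
                         protocol = step)
    }
    if ("vc_ramp" %in% protocols) {
      vr <- s$vc_ramp
      ramp <- protocol_spec("ramp", ramp_rate = vr$rate, ramp_onset = 0,
                            ramp_pre_offset = vr$from)
      dur <- (vr$to - vr$from) / vr$rate
      p <- passive_variant(params)
      cell$vc_ramp <- list(
        basal = simulate_vc_ramp(p, ramp, dur, dt = s$dt_vc,
                                 kv7_blocked = FALSE, noise_sd = s$noise_sigma,
                                 seed = seed_at(ci, 5), cell_id = cell_id),
        xe991 = simulate_vc_ramp(p, ramp, dur, dt = s$dt_vc,
                                 kv7_blocked = TRUE, noise_sd = s$noise_sigma,
                                 seed = seed_at(ci, 5) + 1L,
                                 cell_id = cell_id),
        protocol = ramp)
    }
    if ("events" %in% protocols) {
      rates <- s$event_rates[[genotype]]
      fr <- withr::with_seed(seed_at(ci, 6), jitter_factor(2, s$rate_cv))
      mk <- function(rate, polarity, seed_off) {
        pr <- event_train_params(rate = rate, polarity = polarity)
        generate_event_train(pr, seed = seed_at(ci, 6) + seed_off,
                             cell_id = cell_id, genotype = genotype)
      }
      cell$events <- list(exc = mk(rates[["exc"]] * fr[1], "inward", 1L),
                          inh = mk(rates[["inh"]] * fr[2], "outward", 2L),
                          true_rates = c(exc = rates[["exc"]] * fr[1],
                                         inh = rates[["inh"]] * fr[2]))
    }
    if ("theta_gamma" %in% protocols) {
      sup <- s$suppression[[genotype]]
      cell$theta_gamma <- list(
        test = simulate_theta_gamma(p_base = s$p_base, s = sup,
                                    n_trials = s$n_tg_trials,
                                    with_gamma = TRUE,
                                    seed = seed_at(ci, 7),
                                    cell_id = cell_id, genotype = genotype),
        control = simulate_theta_gamma(p_base = s$p_base, s = sup,
                                       n_trials = s$n_tg_trials,
                                       with_gamma = FALSE,
                                       seed = seed_at(ci, 7) + 1L,
                                       cell_id = cell_id,
                                       genotype = genotype),
        true_s = sup)
    }
    if ("cpsc" %in% protocols) {
      cell$cpsc <- compose_cpsc(
        epsc_peak = s$epsc_peak_pa,
        ipsc_peak = s$ipsc_peak_pa[[genotype]],
        seed = seed_at(ci, 8), cell_id = cell_id, genotype = genotype)
    }
    cell$record <- cell_record(cell_id, genotype = genotype,
                               cell_type = "MC",
                               capacitance = params$C,
                               rmp = params$E_leak)
    cell
  })
  structure(list(cells = cells, n_per_group = n_per_group, seed = seed,
                 protocols = protocols, settings = s),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d WT + %d KO cells, protocols: %s, seed %d>\n",
              x$n_per_group, x$n_per_group,
              paste(x$protocols, collapse = ", "), x$seed))
  invisible(x)
}
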