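# Cohort-level analysis stages and the reproducible pipeline driver. Every
# stage consumes the synthetic cohort (or user-supplied data prepared in
# the same shape) and emits per-cell metrics in a common long format:
# cell_id, group, metric, value.

metric_rows <- function(cell_id, group, ...) {
  vals <- list(...)
  data.frame(cell_id = cell_id, group = group,
             metric = names(vals),
             value = unlist(vals, use.names = FALSE))
}

#' Per-cell AP metrics from the cohort ramp protocol
#'
#' Mean over ramp trials of: AP count in the depolarizing-ramp window,
#' first-AP threshold, rheobase, rheobase charge, and first-AP waveform
#' kinetics.
#'
#' @param cohort a [make_cohort] result including the `ramp` protocol.
#' @return long metrics data frame.
#' @export
analyze_cohort_ap <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$cells, function(cell) {
    if (is.null(cell$ramp)) return(NULL)
    win <- cell$ramp$count_window
    per_trial <- lapply(cell$ramp$trials, function(tr) {
      fs <- ap_feature_set(tr$trace, protocol = cell$ramp$protocol)
      aps <- fs$per_ap
      n_in <- if (nrow(aps)) sum(aps$t_peak_ms >= win[1] &
                                   aps$t_peak_ms <= win[2]) else 0
      first <- if (nrow(aps)) aps[1, ] else NULL
      list(n = n_in,
           v_th = if (!is.null(first)) first$v_th_mv else NA_real_,
           rheo = fs$summary$rheobase_pa, charge = fs$summary$charge_pc,
           rise = if (!is.null(first)) first$max_rise_mvms else NA_real_,
           dur = if (!is.null(first)) first$duration_ms else NA_real_)
    })
    g <- function(f) mean(vapply(per_trial, function(x)
      as.numeric(x[[f]]), numeric(1)), na.rm = TRUE)
    metric_rows(cell$cell_id, cell$genotype,
                ramp_ap_count = g("n"), ap_threshold_mv = g("v_th"),
                rheobase_pa = g("rheo"), rheobase_charge_pc = g("charge"),
                max_rise_mvms = g("rise"), ap_duration_ms = g("dur"))
  }))
}

#' Per-cell Kv7 metrics: input-resistance change and I-V density
#'
#' Input resistance at -45 mV before and during Kv7 block (percent
#' increase), and the XE991-sensitive current density at -45 mV from the
#' ramp I-V curve.
#'
#' @param cohort a [make_cohort] result with `rin45` and/or `vc_ramp`.
#' @return long metrics data frame.
#' @export
analyze_cohort_kv7 <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$cells, function(cell) {
    out <- NULL
    if (!is.null(cell$rin45)) {
      pb <- passive_props(cell$rin45$basal$trace,
                          protocol = cell$rin45$protocol)
      px <- passive_props(cell$rin45$xe991$trace,
                          protocol = cell$rin45$protocol)
      rc <- rin_change(pb$r_in_mohm, px$r_in_mohm)
      out <- rbind(out, metric_rows(cell$cell_id, cell$genotype,
                                    rin45_basal_mohm = rc$basal,
                                    rin45_xe991_mohm = rc$treated,
                                    rin45_increase_pct = rc$percent))
    }
    if (!is.null(cell$vc_ramp)) {
      diff_tr <- subtract_conditions(cell$vc_ramp$basal$trace,
                                     cell$vc_ramp$xe991$trace)
      iv <- build_iv_curve(diff_tr, cell$vc_ramp$basal$command,
                           capacitance_pf = cell$params$C)
      d45 <- iv$curve$density_pa_pf[iv$curve$voltage_mv == -45]
      out <- rbind(out, metric_rows(cell$cell_id, cell$genotype,
                                    kv7_density_m45_pa_pf =
                                      if (length(d45)) d45 else NA_real_))
    }
    out
  }))
}

#' Per-cell synaptic-event metrics and E/I ratio
#'
#' Detects events in the excitatory (inward) and inhibitory (outward)
#' traces at the standard 10 pA threshold and reports rates and the
#' frequency-based E/I ratio.
#'
#' @param cohort a [make_cohort] result including `events`.
#' @return long metrics data frame.
#' @export
analyze_cohort_events <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$cells, function(cell) {
    if (is.null(cell$events)) return(NULL)
    exc <- detect_events(cell$events$exc$trace, "inward")
    inh <- detect_events(cell$events$inh$trace, "outward")
    ei <- ei_ratio(event_rate(exc)$hz, event_rate(inh)$hz)
    metric_rows(cell$cell_id, cell$genotype,
                sepsc_per_min = event_rate(exc)$per_min,
                sipsc_per_min = event_rate(inh)$per_min,
                ei_freq = ei$ratio)
  }))
}

#' Per-cell theta-gamma suppression metrics
#'
#' First-second-bin AP probability in the gamma-preceded (test) train, and
#' its ratio to the control train.
#'
#' @param cohort a [make_cohort] result including `theta_gamma`.
#' @return long metrics data frame.
#' @export
analyze_cohort_osc <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$cells, function(cell) {
    if (is.null(cell$theta_gamma)) return(NULL)
    tg <- cell$theta_gamma
    test <- ap_probability_from_raster(tg$test$raster, tg$test$protocol)
    ctrl <- ap_probability_from_raster(tg$control$raster,
                                       tg$control$protocol)
    gsi <- gamma_suppression_index(ctrl, test)
    metric_rows(cell$cell_id, cell$genotype,
                tg_first_bin_p = test$bins$p[1],
                tg_first_bin_ratio = gsi$ratio[1])
  }))
}

#' Per-cell compound-PSC decomposition metrics
#'
#' @param cohort a [make_cohort] result including `cpsc`.
#' @return long metrics data frame.
#' @export
analyze_cohort_cpsc <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$cells, function(cell) {
    if (is.null(cell$cpsc)) return(NULL)
    tpl <- build_epsc_template(cell$cpsc$template_sweeps)
    dec <- suppressWarnings(decompose_cpsc(cell$cpsc$cpsc_sweeps, tpl))
    metric_rows(cell$cell_id, cell$genotype,
                cpsc_ei_peak = dec$ei_peak,
                cpsc_ei_charge = dec$ei_charge,
                cpsc_excitation_window_ms = dec$excitation_window_ms)
  }))
}

#' All per-cell metrics for a cohort
#' @param cohort a [make_cohort] result.
#' @return long metrics data frame combining every simulated protocol.
#' @export
analyze_cohort <- function(cohort) {
  parts <- list(
    if ("ramp" %in% cohort$protocols) analyze_cohort_ap(cohort),
    if (any(c("rin45", "vc_ramp") %in% cohort$protocols))
      analyze_cohort_kv7(cohort),
    if ("events" %in% cohort$protocols) analyze_cohort_events(cohort),
    if ("theta_gamma" %in% cohort$protocols) analyze_cohort_osc(cohort),
    if ("cpsc" %in% cohort$protocols) analyze_cohort_cpsc(cohort))
  do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
}

PIPELINE_STAGES <- c("synth", "ap", "kv7", "events", "cpsc", "osc",
                     "stats", "all")

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order on a synthetic cohort and writes
#' per-stage metric tables plus a combined summary. Identical config and
#' seed give identical outputs. The `synth` stage (or `all`) must precede
#' analysis stages; an analysis stage without data is a config error.
#'
#' @param config a named list, or a path to a YAML or JSON config file.
#'   Recognized fields: `stages` (subset of synth, ap, kv7, events, cpsc,
#'   osc, stats, all), `seed` (default 0, recorded in the report),
#'   `n_per_group` (default 15), `kv7_scale` (default 1.5), `out` (output
#'   directory; overridden by the `out` argument).
#' @param out output directory; created if missing.
#' @return invisibly, a list with `metrics`, `summary` (when computed) and
#'   the effective `config`.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else if (requireNamespace("yaml", quietly = TRUE))
      yaml::read_yaml(config)
    else stop("run_pipeline: yaml package needed to read ", config)
  }
  stopifnot(is.list(config))
  stages <- unlist(config$stages)
  if (is.null(stages)) stop("run_pipeline: config must name stages")
  if (!all(stages %in% PIPELINE_STAGES))
    stop("run_pipeline: unknown stage(s): ",
         paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "))
  if ("all" %in% stages)
    stages <- c("synth", "ap", "kv7", "events", "cpsc", "osc", "stats")
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  n_per_group <- if (is.null(config$n_per_group)) 15L else
    as.integer(config$n_per_group)
  kv7_scale <- if (is.null(config$kv7_scale)) 1.5 else config$kv7_scale
  out <- out %||% config$out
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  analysis_stages <- intersect(stages,
                               c("ap", "kv7", "events", "cpsc", "osc"))
  need <- c(ap = "ramp", kv7 = "vc_ramp", events = "events",
            cpsc = "cpsc", osc = "theta_gamma")
  cohort <- NULL
  if ("synth" %in% stages) {
    protocols <- unique(c("ramp", "rin45",
                          unname(need[analysis_stages])))
    if (!length(analysis_stages))
      protocols <- c("ramp", "rin45", "vc_ramp", "events", "theta_gamma")
    wt <- membrane_params(genotype = "WT")
    cohort <- make_cohort(n_per_group = n_per_group, wt_params = wt,
                          ko_pars = ko_params(wt, kv7_scale),
                          protocols = protocols, seed = seed)
  } else if (length(analysis_stages) || "stats" %in% stages) {
    stop("run_pipeline: analysis stages need the synth stage ",
         "(no external input configured)")
  }
  metrics <- NULL
  run_stage <- list(ap = analyze_cohort_ap, kv7 = analyze_cohort_kv7,
                    events = analyze_cohort_events,
                    cpsc = analyze_cohort_cpsc, osc = analyze_cohort_osc)
  for (st in analysis_stages) {
    m <- run_stage[[st]](cohort)
    metrics <- rbind(metrics, m)
    if (!is.null(out))
      utils::write.csv(m, file.path(out, paste0(st, "_metrics.csv")),
                       row.names = FALSE)
  }
  summary_df <- NULL
  if ("stats" %in% stages) {
    if (is.null(metrics))
      stop("run_pipeline: stats stage needs at least one analysis stage")
    summary_df <- summary_table(metrics, group_levels = c("WT", "KO"))
    if (!is.null(out))
      utils::write.csv(summary_df, file.path(out, "summary.csv"),
                       row.names = FALSE)
  }
  if (!is.null(out))
    jsonlite::write_json(
      list(seed = seed, stages = stages, n_per_group = n_per_group,
           kv7_scale = kv7_scale, schema_version = SCHEMA_VERSION),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, summary = summary_df,
                 config = list(stages = stages, seed = seed,
                               n_per_group = n_per_group,
                               kv7_scale = kv7_scale)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
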