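test_that("AP detection: flat trace, truth recovery, and the
          2 ms merge rule", {
  flat <- trace(rep(-65, 5000), dt = 0.1, signal_kind = "voltage")
  expect_equal(nrow(detect_aps(flat)), 0L)

  times <- c(100, 150, 230, 400, 410, 500, 580, 660, 700, 790, 850, 900)
  tr <- spike_train_trace(times)
  expect_equal(nrow(detect_aps(tr)), 12L)

  # spiking-model truth: detected count equals true spike count
  ramp <- protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 50,
                        ramp_pre_offset = -50)
  sim <- simulate_membrane(membrane_params(), ramp, 1800, seed = 2)
  expect_equal(nrow(detect_aps(sim$trace)),
               length(sim$truth$spike_times))

  # two peaks 1 ms apart merge into one AP
  twin <- spike_train_trace(c(100, 101), dt = 0.02)
  expect_equal(nrow(detect_aps(twin)), 1L)
})

test_that("third-derivative threshold lands at a constructed slope
          discontinuity", {
  dt <- 0.02
  t <- seq(0, 55, by = dt)
  t_star <- 50
  blend <- 0.25       # C1 smoothing half-width, ms
  dvdt <- 1 + 19 * pmin(1, pmax(0, (t - (t_star - blend)) / (2 * blend)))
  v <- -80 + cumsum(dvdt) * dt
  tr <- trace(v, dt = dt, signal_kind = "voltage")
  win <- list(start_idx = which.min(abs(t - 44)),
              peak_idx = length(t), end_idx = length(t))
  th <- ap_threshold(tr, win)
  expect_true(th$ok)
  expect_lt(abs(th$t_th - t_star), 0.5)
})

test_that("a pure sine window yields no detectable threshold", {
  dt <- 0.02
  t <- seq(0, 20, by = dt)
  v <- -50 + 30 * sin(2 * pi * t / 10)
  tr <- trace(v, dt = dt, signal_kind = "voltage")
  ip <- which.max(v[t < 5])
  th <- ap_threshold(tr, list(start_idx = 1L, peak_idx = ip,
                              end_idx = ip + 100L))
  expect_false(th$ok)
  expect_true(is.na(th$v_th))
})

test_that("model-AP threshold agrees with the dV/dt = 20 mV/ms oracle
          within 3 mV", {
  ramp <- protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 50,
                        ramp_pre_offset = -50)
  sim <- simulate_membrane(membrane_params(), ramp, 1500, seed = 1)
  tr <- sim$trace
  aps <- detect_aps(tr)
  expect_gt(nrow(aps), 0)
  th <- ap_threshold(tr, aps[1, ])
  v <- tr$values
  dv <- diff(v) / tr$dt
  i20 <- which(dv[1:(aps$peak_idx[1] - 1)] >= 20)[1]
  expect_lt(abs(th$v_th - v[i20]), 3)
})

test_that("rheobase and charge follow the ramp closed forms", {
  ramp0 <- protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 0)
  rc <- rheobase_and_charge(ramp0, t_th = 1000)
  expect_equal(rc$rheobase_pa, 150, tolerance = 1e-9)
  expect_equal(rc$charge_pc, 75, tolerance = 1e-9)
  rc0 <- rheobase_and_charge(ramp0, t_th = 0)
  expect_equal(rc0$rheobase_pa, 0)
  expect_equal(rc0$charge_pc, 0)
  expect_error(rheobase_and_charge(
    protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 100), t_th = 50),
    "precedes ramp onset")
})

test_that("hyperpolarizing-onset charge equals the dense numeric
          integral over the depolarizing segment", {
  ramp <- protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 100,
                        ramp_pre_offset = -50)
  t_zero <- 100 + 50 / 0.15
  t_th <- t_zero + 800
  rc <- rheobase_and_charge(ramp, t_th)
  tt <- seq(t_zero, t_th, length.out = 200001)
  ii <- -50 + 0.15 * (tt - 100)
  oracle <- trapz(ii, tt) / 1000
  expect_equal(rc$charge_pc, oracle, tolerance = 1e-9)
  # charge grows monotonically with threshold time
  charges <- vapply(seq(t_zero + 10, t_zero + 1500, by = 100),
                    function(tth) rheobase_and_charge(ramp, tth)$charge_pc,
                    numeric(1))
  expect_true(all(diff(charges) > 0))
})

test_that("idealized triangle AP yields the geometric waveform
          features", {
  dt <- 0.01
  up <- seq(-45, 35, by = 80 * dt)          # 1 ms upstroke, 80 mV/ms
  down <- seq(35, -55, by = -45 * dt)       # 2 ms downstroke
  base <- rep(-65, 500)
  v <- c(base, seq(-65, -45, by = 2 * dt)[-1], up[-1], down[-1],
         rep(-55, 300))
  tr <- trace(v, dt = dt, signal_kind = "voltage")
  aps <- detect_aps(tr)
  expect_equal(nrow(aps), 1L)
  wf <- ap_waveform_features(tr, aps[1, ], v_th = -45,
                             t_th = (which.max(v) - 1 - 100) * dt)
  expect_equal(wf$amplitude_mv, 80, tolerance = 0.01)
  expect_equal(wf$rise_ms, 0.8, tolerance = 0.05)
  expect_equal(wf$max_rise_mvms, 80, tolerance = 0.05)
  # -10 mV crossings: up at 35/80 ms before peak minus... symmetric check
  expect_equal(wf$duration_ms, 45 / 80 + 45 / 45, tolerance = 0.05)
})

test_that("waveform features are stable under 4x time refinement", {
  ramp <- protocol_spec("ramp", ramp_rate = 0.15, ramp_onset = 50,
                        ramp_pre_offset = -50)
  p <- membrane_params()
  coarse <- simulate_membrane(p, ramp, 1500, dt = 0.02, seed = 1)
  fine <- simulate_membrane(p, ramp, 1500, dt = 0.005, seed = 1)
  f1 <- ap_feature_set(coarse$trace)$per_ap[1, ]
  f2 <- ap_feature_set(fine$trace)$per_ap[1, ]
  for (col in c("peak_mv", "amplitude_mv", "max_rise_mvms", "rise_ms",
                "fall_ms", "duration_ms")) {
    expect_lt(abs(f1[[col]] - f2[[col]]) / abs(f2[[col]]), 0.02,
              label = paste("refinement drift of", col))
  }
})

test_that("features are invariant to a time-axis shift", {
  sim <- simulate_membrane(membrane_params(),
                           protocol_spec("ramp", ramp_rate = 0.15,
                                         ramp_onset = 50,
                                         ramp_pre_offset = -50),
                           1500, seed = 3)
  tr <- sim$trace
  shifted <- trace(tr$values, dt = tr$dt, t0 = tr$t0 + 5000,
                   signal_kind = "voltage")
  f1 <- ap_feature_set(tr)$per_ap
  f2 <- ap_feature_set(shifted)$per_ap
  expect_equal(f2$t_th_ms - f1$t_th_ms, rep(5000, nrow(f1)))
  expect_equal(f1$v_th_mv, f2$v_th_mv)
  expect_equal(f1$duration_ms, f2$duration_ms)
})

test_that("excitability curve averages trials per potential and flags
          gaps", {
  silent <- trace(rep(-65, 2000), dt = 0.1, signal_kind = "voltage")
  out <- excitability_curve(list(silent, silent, silent, silent),
                            potentials = c(-64, -64, -63, -63))
  expect_equal(out$mean_count, c(0, 0))
  trs <- list(spike_train_trace(c(50, 150, 250)),
              spike_train_trace(c(50, 150, 250, 350)),
              spike_train_trace(c(50, 150, 250, 350, 450)),
              spike_train_trace(c(50, 150, 250, 350)))
  out2 <- excitability_curve(trs, potentials = rep(-60, 4))
  expect_equal(out2$mean_count, 4)
  out3 <- excitability_curve(list(silent, silent),
                             potentials = c(-64, -61))
  expect_equal(attr(out3, "gaps"), c(-63, -62))
})

test_that("passive properties follow Ohm's law and recover a known RC
          cell under noise", {
  mk_step_trace <- function(dv, step_pa, base = -65) {
    v <- c(rep(base, 2000), rep(base + dv, 5000), rep(base, 1000))
    trace(v, dt = 0.1, signal_kind = "voltage")
  }
  st <- protocol_spec("step", step_amplitude = -60, step_onset = 200,
                      step_duration = 500)
  pp <- passive_props(mk_step_trace(-6, -60), st)
  expect_equal(pp$r_in_mohm, 100)
  st2 <- protocol_spec("step", step_amplitude = 60, step_onset = 200,
                       step_duration = 500)
  pp2 <- passive_props(mk_step_trace(3, 60), st2)
  expect_equal(pp2$r_in_mohm, 50)
  expect_error(passive_props(mk_step_trace(-6, -60),
                             protocol_spec("step", step_amplitude = -60,
                                           step_onset = 200,
                                           step_duration = 200)),
               "settled")
  # RC cell: R = 150 Mohm, tau = 15 ms, 0.2 mV noise
  set.seed(4)
  t <- seq(0, 800, by = 0.1)
  vstep <- -60 * 150 / 1000 * (1 - exp(-(t - 200) / 15)) * (t >= 200) *
    (t < 700)
  v <- -65 + vstep + rnorm(length(t), 0, 0.2)
  pp3 <- passive_props(trace(v, dt = 0.1, signal_kind = "voltage"), st)
  expect_lt(abs(pp3$r_in_mohm - 150) / 150, 0.05)
})

test_that("firing-pattern classification applies its decision rule", {
  fast <- spike_train_trace(100 + (0:59) * 10, duration_ms = 800)
  rf <- classify_firing_pattern(fast)
  expect_identical(rf$label, "fast_spiking")
  expect_equal(rf$metrics$max_rate_hz, 100, tolerance = 0.01)
  expect_equal(rf$metrics$adaptation, 1, tolerance = 0.01)

  reg <- spike_train_trace(100 + cumsum(c(0, 20, 24, 29, 35, 42)))
  rr <- classify_firing_pattern(reg)
  expect_identical(rr$label, "regular_spiking")
  expect_equal(rr$metrics$adaptation, 2.1, tolerance = 0.01)
  expect_lt(rr$metrics$isi_cv, 0.5)

  burst_times <- as.vector(outer((0:4) * 10, c(100, 250, 400, 550), "+"))
  st <- classify_firing_pattern(spike_train_trace(sort(burst_times)))
  expect_identical(st$label, "stuttering_like")
  isi <- diff(sort(burst_times))
  expect_gt(sd(isi) / mean(isi), 0.5)   # brute-force CV confirms the rule

  few <- spike_train_trace(c(100, 200))
  expect_identical(classify_firing_pattern(few)$label, "undetermined")
})
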