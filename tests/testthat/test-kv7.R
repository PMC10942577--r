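test_that("condition subtraction is exact, linear, and checks
          alignment", {
  a <- trace(rnorm(100), dt = 0.1, signal_kind = "current")
  expect_equal(subtract_conditions(a, a)$values, rep(0, 100))
  b <- trace(rnorm(100), dt = 0.1, signal_kind = "current")
  common <- rnorm(100)
  d1 <- subtract_conditions(a, b)$values
  a2 <- trace(a$values + common, dt = 0.1, signal_kind = "current")
  b2 <- trace(b$values + common, dt = 0.1, signal_kind = "current")
  expect_equal(subtract_conditions(a2, b2)$values, d1, tolerance = 1e-12)
  short <- trace(rnorm(50), dt = 0.1, signal_kind = "current")
  expect_error(subtract_conditions(a, short), "length")
  wrongdt <- trace(rnorm(100), dt = 0.2, signal_kind = "current")
  expect_error(subtract_conditions(a, wrongdt), "dt")
})

test_that("subtraction recovers an injected Boltzmann component to
          machine precision", {
  p <- passive_params(g_kv7_max = 2, tau_kv7 = 0)
  ramp <- protocol_spec("ramp", ramp_rate = 0.02, ramp_onset = 0,
                        ramp_pre_offset = -95)
  basal <- simulate_vc_ramp(p, ramp, 5000)
  treated <- simulate_vc_ramp(p, ramp, 5000, kv7_blocked = TRUE)
  d <- subtract_conditions(basal$trace, treated$trace)
  expect_equal(d$values, basal$truth$i_kv7, tolerance = 1e-12)
})

test_that("5-trial-averaged subtraction noise stays within the
          propagation bound", {
  p <- passive_params(g_kv7_max = 2)
  ramp <- protocol_spec("ramp", ramp_rate = 0.02, ramp_onset = 0,
                        ramp_pre_offset = -95)
  avg_of <- function(blocked, seeds) {
    mats <- vapply(seeds, function(s)
      simulate_vc_ramp(p, ramp, 2000, kv7_blocked = blocked, noise_sd = 5,
                       seed = s)$trace$values,
      numeric(round(2000 / 0.02) + 1))
    rowMeans(mats)
  }
  b <- avg_of(FALSE, 1:5)
  x <- avg_of(TRUE, 6:10)
  clean_b <- simulate_vc_ramp(p, ramp, 2000, kv7_blocked = FALSE)$trace$values
  clean_x <- simulate_vc_ramp(p, ramp, 2000, kv7_blocked = TRUE)$trace$values
  resid <- (b - x) - (clean_b - clean_x)
  rms <- sqrt(mean(resid^2))
  expect_lt(rms, 5 * sqrt(2 / 5) * 1.1)
})

test_that("I-V construction normalizes by capacitance and averages the
          command window", {
  n <- 250001
  cmd <- trace(seq(-95, 5, length.out = n), dt = 0.02,
               signal_kind = "voltage")
  cur <- trace(rep(100, n), dt = 0.02, signal_kind = "current")
  iv <- build_iv_curve(cur, cmd, capacitance_pf = 100)
  expect_equal(iv$curve$voltage_mv, seq(-95, 5, by = 5))
  expect_true(all(abs(iv$curve$density_pa_pf - 1) < 1e-12))
  # widening the window on noise-free data leaves the curve unchanged
  p <- passive_params(g_kv7_max = 2, tau_kv7 = 0)
  ramp <- protocol_spec("ramp", ramp_rate = 0.02, ramp_onset = 0,
                        ramp_pre_offset = -95)
  sim <- simulate_vc_ramp(p, ramp, 5000)
  iv1 <- build_iv_curve(sim$trace, sim$command, 150, window_mv = 0.01)
  iv2 <- build_iv_curve(sim$trace, sim$command, 150, window_mv = 1)
  expect_equal(iv1$curve$density_pa_pf, iv2$curve$density_pa_pf,
               tolerance = 1e-3)
})

test_that("XE991-sensitive density matches the Boltzmann closed form at
          -45 mV and KO/WT curves scale by the conductance factor", {
  ramp <- protocol_spec("ramp", ramp_rate = 0.02, ramp_onset = 0,
                        ramp_pre_offset = -95)
  run_iv <- function(gmax) {
    p <- passive_params(g_kv7_max = gmax, tau_kv7 = 0)
    b <- simulate_vc_ramp(p, ramp, 5000)
    x <- simulate_vc_ramp(p, ramp, 5000, kv7_blocked = TRUE)
    build_iv_curve(subtract_conditions(b$trace, x$trace), b$command, 150)
  }
  iv_wt <- run_iv(2)
  vs <- iv_wt$curve$voltage_mv
  a45 <- 1 / (1 + exp((-40 + 45) / 8))
  expect_equal(iv_wt$curve$density_pa_pf[vs == -45],
               2 * a45 * 45 / 150, tolerance = 1e-4)
  iv_ko <- run_iv(3)
  nz <- abs(iv_wt$curve$density_pa_pf) > 1e-9
  expect_equal(iv_ko$curve$density_pa_pf[nz] /
                 iv_wt$curve$density_pa_pf[nz],
               rep(1.5, sum(nz)), tolerance = 1e-9)
  # sub-activation voltages carry essentially no density
  low <- vs <= -80
  expect_lt(max(abs(iv_wt$curve$density_pa_pf[low])), 0.01)
})

test_that("holding-current and membrane-potential shifts difference the
          segment means", {
  mk <- function(mean_val, kind) trace(rep(mean_val, 120000), dt = 0.1,
                                       signal_kind = kind)
  hs <- holding_shift(mk(50, "current"), mk(20, "current"))
  expect_equal(hs$delta, -30)
  expect_equal(holding_shift(mk(50, "current"), mk(50, "current"))$delta, 0)
  expect_error(holding_shift(trace(rep(1, 100), dt = 0.1,
                                   signal_kind = "current"),
                             mk(20, "current")), "shorter")
  vs <- vm_shift(mk(-45, "voltage"), mk(-41, "voltage"))
  expect_equal(vs$delta, 4)
  # closed-form recovery of the Kv7 standing current at -45 mV
  p <- passive_params(g_kv7_max = 2, tau_kv7 = 0)
  i_kv7_45 <- 2 * (1 / (1 + exp((-40 + 45) / 8))) * (-45 + 90)
  basal <- mk(holding_current_for(p, -45), "current")
  blocked <- passive_params(g_kv7_max = 0)
  treated <- mk(holding_current_for(blocked, -45), "current")
  hs2 <- holding_shift(basal, treated)
  expect_equal(hs2$delta, -i_kv7_45, tolerance = 0.02)
})

test_that("input-resistance change reports percent increase and the KO
          cohort shows the stronger XE991 effect", {
  rc <- rin_change(100, 150)
  expect_equal(rc$percent, 50)
  expect_equal(rin_change(120, 120)$percent, 0)
  expect_error(rin_change(0, 100), "> 0")

  co <- make_cohort(n_per_group = 6, protocols = "rin45", seed = 3)
  m <- analyze_cohort_kv7(co)
  inc <- m[m$metric == "rin45_increase_pct", ]
  expect_gt(mean(inc$value[inc$group == "KO"]),
            mean(inc$value[inc$group == "WT"]))
})
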