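test_that("template from identical noise-free sweeps equals a single
          sweep, and the >= 20 sweep rule is enforced", {
  cc <- compose_cpsc(ipsc_peak = 0, amp_cv = 0, noise_sd = 0,
                     n_sweeps = 1, n_template = 20, seed = 1)
  tpl <- build_epsc_template(cc$template_sweeps)
  expect_equal(tpl$waveform, cc$template_sweeps[[1]]$values,
               tolerance = 1e-12)
  expect_equal(tpl$n_events, 20L)
  expect_error(build_epsc_template(cc$template_sweeps[1:19]),
               "uncontaminated")
})

test_that("template peak tracks the true mean peak under jitter and
          noise", {
  cc <- compose_cpsc(epsc_peak = -120, ipsc_peak = 0, amp_cv = 0.1,
                     noise_sd = 2, n_sweeps = 1, n_template = 25,
                     seed = 2)
  tpl <- build_epsc_template(cc$template_sweeps)
  true_mean_peak <- -120 * mean(cc$truth$template_scales)
  expect_lt(abs(tpl$peak_pa - true_mean_peak) / abs(true_mean_peak), 0.03)
})

test_that("approximating segment sits at 25-65% depth within 2.5 ms,
          verified against the kernel inverse", {
  dt <- 0.05
  t <- seq(-50, 150, by = dt)
  wf <- -100 * biexp_kernel(t - 0.5, 0.5, 6)   # early-onset EPSC
  seg <- find_approximating_segment(wf, t)
  depth_frac <- -wf[seg] / max(-wf)
  expect_true(all(depth_frac >= 0.25 & depth_frac <= 0.65))
  expect_true(all(t[seg] <= 2.5))
  expect_gte(length(seg), 2)
  # dense-grid oracle for the 25% and 65% crossing times on the rise
  tq <- seq(0.5, t[which.min(wf)], by = 1e-4)
  kq <- biexp_kernel(tq - 0.5, 0.5, 6)
  t25 <- tq[which(kq >= 0.25)[1]]
  t65 <- tq[which(kq >= 0.65)[1]]
  expect_lt(abs(min(t[seg]) - t25), 2 * dt)
  expect_lt(abs(max(t[seg]) - min(t65, 2.5)), 2 * dt)
  # upward-only waveform has no excitatory limb
  expect_error(find_approximating_segment(abs(wf), t),
               class = "segment_not_found")
})

test_that("a cPSC that is a scaled template decomposes with uniform
          scale factors and a null IPSC", {
  cc <- compose_cpsc(epsc_peak = -120, ipsc_peak = 0, amp_cv = 0,
                     noise_sd = 0, n_sweeps = 25, n_template = 20,
                     seed = 3)
  tpl <- build_epsc_template(cc$template_sweeps)
  scaled <- lapply(cc$cpsc_sweeps, function(s)
    trace(1.8 * s$values, dt = s$dt, t0 = s$t0, signal_kind = "current"))
  dec <- decompose_cpsc(scaled, tpl)
  expect_lt(sd(dec$scale_factors) / mean(dec$scale_factors), 1e-6)
  expect_equal(mean(dec$scale_factors), 1.8, tolerance = 1e-9)
  expect_lt(max(abs(dec$ipsc)) / abs(dec$epsc_peak_pa), 1e-9)
})

test_that("noise-free decomposition recovers the IPSC peak and E/I
          within 10%, and the subtraction identity is exact", {
  cc <- compose_cpsc(epsc_peak = -120, ipsc_peak = 80, epsc_latency = 2,
                     ipsc_latency = 4, amp_cv = 0, noise_sd = 0,
                     n_sweeps = 25, n_template = 20, seed = 4)
  tpl <- build_epsc_template(cc$template_sweeps)
  dec <- decompose_cpsc(cc$cpsc_sweeps, tpl)
  expect_lt(abs(dec$ipsc_peak_pa - 80) / 80, 0.10)
  expect_lt(abs(dec$ei_peak - 1.5) / 1.5, 0.10)
  expect_equal(dec$epsc + dec$ipsc, dec$cpsc, tolerance = 1e-14)
  expect_equal(min(dec$epsc_norm), -1, tolerance = 1e-12)
})

test_that("decomposition with 3 pA noise and 25 sweeps stays within 15%
          of the true IPSC peak", {
  cc <- compose_cpsc(epsc_peak = -120, ipsc_peak = 80, amp_cv = 0.1,
                     noise_sd = 3, n_sweeps = 25, n_template = 25,
                     seed = 5)
  tpl <- build_epsc_template(cc$template_sweeps)
  dec <- suppressWarnings(decompose_cpsc(cc$cpsc_sweeps, tpl))
  true_peak <- max(cc$truth$ipsc)
  expect_lt(abs(dec$ipsc_peak_pa - true_peak) / true_peak, 0.15)
})

test_that("decomposition is invariant to a constant baseline offset and
          agrees between averaged and per-sweep scaling", {
  cc <- compose_cpsc(amp_cv = 0, noise_sd = 0, n_sweeps = 25,
                     n_template = 20, seed = 6)
  tpl <- build_epsc_template(cc$template_sweeps)
  dec <- decompose_cpsc(cc$cpsc_sweeps, tpl)
  shifted <- lapply(cc$cpsc_sweeps, function(s)
    trace(s$values + 37.5, dt = s$dt, t0 = s$t0, signal_kind = "current"))
  dec2 <- decompose_cpsc(shifted, tpl)
  expect_equal(dec2$ipsc, dec$ipsc, tolerance = 1e-9)
  dec3 <- decompose_cpsc(cc$cpsc_sweeps, tpl, per_sweep = TRUE)
  expect_equal(dec3$ipsc_peak_pa, dec$ipsc_peak_pa, tolerance = 0.01)
})

test_that("excitation window matches a dense root-finding oracle for an
          isolated EPSC and shrinks under an overlapping IPSC", {
  dt <- 0.05
  t <- seq(-50, 150, by = dt)
  wf <- -100 * biexp_kernel(t - 2, 0.5, 5)
  ew <- excitation_window(wf, t)
  # oracle: support where kernel depth exceeds the same relative floor
  floor_frac <- 0.005
  tq <- seq(0, 150, by = 1e-4)
  kq <- biexp_kernel(tq - 2, 0.5, 5)
  above <- tq[kq > floor_frac]
  oracle <- max(above) - min(above)
  expect_lt(abs(ew$window_ms - oracle), 0.2)

  with_ipsc <- wf + 80 * biexp_kernel(t - 4, 1.5, 15)
  ew2 <- excitation_window(with_ipsc, t)
  expect_lt(ew2$window_ms, ew$window_ms)

  flat <- excitation_window(rep(0, length(t)), t)
  expect_false(flat$defined)
})

test_that("E/I ratios from the decomposition follow peak and charge
          definitions across an amplitude grid", {
  expect_equal(dentephys:::ei_from_components(
    c(0, -100, 0), c(0, 50, 0), c(0, 1, 2))$ei_peak, 2)
  # mirrored components have charge ratio 1
  dt <- 0.05
  t <- seq(-10, 150, by = dt)
  e <- -biexp_kernel(t - 2, 0.5, 5) * 100
  expect_equal(dentephys:::ei_from_components(e, -e, t)$ei_charge, 1)
  for (ratio in c(0.25, 0.5, 1, 2)) {
    cc <- compose_cpsc(epsc_peak = -120, ipsc_peak = 120 * ratio,
                       amp_cv = 0, noise_sd = 0, n_sweeps = 25,
                       n_template = 20, seed = 7)
    tpl <- build_epsc_template(cc$template_sweeps)
    dec <- decompose_cpsc(cc$cpsc_sweeps, tpl)
    truth <- dentephys:::ei_from_components(cc$truth$epsc, cc$truth$ipsc,
                                            cc$truth$time_ms)
    expect_lt(abs(dec$ei_charge - truth$ei_charge) / truth$ei_charge,
              0.10, label = paste("charge E/I at ratio", ratio))
  }
})
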