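test_that("detection threshold separates -12 pA from -8 pA events", {
  dt <- 0.1
  t <- seq(0, 2000, by = dt)
  v <- -12 * biexp_kernel(t - 500) - 8 * biexp_kernel(t - 1200)
  tr <- trace(v, dt = dt, signal_kind = "current")
  el <- detect_events(tr, "inward", threshold_pa = 10)
  expect_equal(nrow(el$events), 1L)
  expect_lt(abs(el$events$time_ms[1] - 500), 2)
  expect_lte(el$events$amplitude_pa[1], -10)
})

test_that("detection recall and precision exceed 0.98 on a sparse
          fixed-seed train", {
  pr <- event_train_params(rate = 50 / 30, duration = 30,
                           amp_meanlog = log(30), amp_sdlog = 0,
                           noise_sd = 2)
  g <- generate_event_train(pr, seed = 9)
  el <- detect_events(g$trace, "inward")
  m <- match_events(el$events$time_ms, g$truth$time_ms)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)
})

test_that("pure 2 pA noise produces at most one false event per 30 s", {
  for (s in c(21, 22, 23)) {
    g <- generate_event_train(event_train_params(rate = 0, duration = 30),
                              seed = s)
    expect_lte(nrow(detect_events(g$trace, "inward")$events), 1)
  }
})

test_that("raising the threshold never increases the event count", {
  g <- generate_event_train(event_train_params(rate = 8, duration = 20),
                            seed = 31)
  counts <- vapply(c(10, 15, 20, 30), function(thr)
    nrow(detect_events(g$trace, "inward", threshold_pa = thr)$events),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("instantaneous frequencies follow 1/ISI with per-later-event
          assignment", {
  expect_equal(instantaneous_frequencies(c(0, 500, 1000)), c(2, 2))
  expect_equal(instantaneous_frequencies(c(123)), numeric(0))
  # against truth ISIs of a generated train
  g <- generate_event_train(event_train_params(rate = 10, duration = 10),
                            seed = 41)
  truth_f <- 1000 / diff(g$truth$time_ms)
  expect_equal(instantaneous_frequencies(g$truth$time_ms), truth_f)
})

test_that("frequency distribution is per-cell normalized and conserves
          the pooled count", {
  mk_el <- function(times) {
    structure(list(events = data.frame(
      time_ms = times, amplitude_pa = rep(-20, length(times)),
      inst_freq_hz = c(NA, 1000 / diff(times)),
      overlap = FALSE),
      threshold_pa = 10, polarity = "inward", duration_s = 30),
      class = "event_list")
  }
  # inter-event intervals giving inst freqs 1, 3, 3, 5 Hz
  t1 <- cumsum(c(0, 1000, 1000 / 3, 1000 / 3, 200))
  fd <- frequency_distribution(list(mk_el(t1)), bin_hz = 2)
  expect_equal(fd$counts_per_cell[1:3], c(1, 2, 1))
  # two identical cells leave the per-cell histogram unchanged
  fd2 <- frequency_distribution(list(mk_el(t1), mk_el(t1)), bin_hz = 2)
  expect_equal(fd2$counts_per_cell, fd$counts_per_cell)
  # conservation: sum(normalized) * n_cells = pooled count, exactly
  set.seed(51)
  cells <- lapply(1:5, function(i) mk_el(sort(runif(30, 0, 30000))))
  fdr <- frequency_distribution(cells)
  expect_identical(sum(fdr$counts_per_cell) * fdr$n_cells,
                   as.numeric(fdr$n_pooled))
})

test_that("cumulative probability is a right-continuous ECDF ending at
          1", {
  cp <- cumulative_probability(c(2, 2, 4))
  expect_equal(cp$value, c(2, 4))
  expect_equal(cp$cum_prob, c(2 / 3, 1))
  set.seed(61)
  cp2 <- cumulative_probability(rlnorm(100))
  expect_true(all(diff(cp2$cum_prob) >= 0))
  expect_gte(cp2$cum_prob[1], 1 / 100)
  expect_equal(cp2$cum_prob[nrow(cp2)], 1)
  expect_error(cumulative_probability(numeric(0)), "empty")
})

test_that("event rates and E/I ratios compute in both unit systems", {
  g <- generate_event_train(event_train_params(rate = 1, duration = 30),
                            seed = 71)
  el <- detect_events(g$trace, "inward")
  r <- event_rate(el)
  expect_equal(r$per_min, r$hz * 60)
  expect_equal(ei_ratio(10, 5)$ratio, 2)
  expect_equal(ei_ratio(4, 4)$ratio, 1)
  und <- ei_ratio(10, 0)
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
})

test_that("Poisson rate recovery: detected rate within 3 SE of truth
          over seeds", {
  rates <- vapply(1:50, function(s) {
    g <- generate_event_train(event_train_params(rate = 10, duration = 10),
                              seed = 100 + s)
    event_rate(detect_events(g$trace, "inward"))$hz
  }, numeric(1))
  # detection loses ~2-4% to merges; accept a band around the true rate
  expect_gt(mean(rates), 10 * 0.93)
  expect_lt(mean(rates), 10 * 1.03)
})

test_that("normalized frequency time course reports percent of basal", {
  set.seed(81)
  base_times <- sort(runif(500, 0, 300000))        # 100/min for 5 min
  drug_times <- sort(runif(250, 300000, 600000))   # 50/min
  el <- structure(list(events = data.frame(
    time_ms = c(base_times, drug_times),
    amplitude_pa = -20, inst_freq_hz = NA, overlap = FALSE),
    threshold_pa = 10, polarity = "inward", duration_s = 600),
    class = "event_list")
  nf <- normalized_frequency_timecourse(el, c(0, 300000), c(300000, 600000))
  expect_equal(nf$percent_of_basal, 50)
  expect_error(normalized_frequency_timecourse(el, c(0, 300000),
                                               c(200000, 400000)),
               "overlap")
})

test_that("Poisson thinning to 47.6% of basal is recovered on average", {
  pct <- vapply(1:60, function(s) {
    withr::with_seed(900 + s, {
      nb <- rpois(1, 500)
      nd <- rpois(1, 500 * 0.476)
      el <- structure(list(events = data.frame(
        time_ms = sort(c(runif(nb, 0, 300000),
                         runif(nd, 300000, 600000))),
        amplitude_pa = -20, inst_freq_hz = NA, overlap = FALSE),
        threshold_pa = 10, polarity = "inward", duration_s = 600),
        class = "event_list")
      normalized_frequency_timecourse(el, c(0, 300000),
                                      c(300000, 600000))$percent_of_basal
    })
  }, numeric(1))
  se <- sd(pct) / sqrt(length(pct))
  expect_lt(abs(mean(pct) - 47.6), 3 * se + 0.5)
})
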