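test_that("spontaneous AP frequency is events over duration", {
  fs <- 20000
  # 45 pasted spikes in 30 s -> 1.5 Hz
  v <- rep(-65, 30 * fs)
  at <- round(seq(0.5, 29.5, length.out = 45) * fs)
  for (j in at) v[j:(j + 10)] <- c(seq(-65, 30, length.out = 6),
                                   seq(20, -70, length.out = 5))
  res <- detect_saps(v, fs)
  expect_equal(res$frequency_hz, 1.5)
  expect_equal(length(res$times_s), 45)
  silent <- detect_saps(rep(-70, fs), fs)
  expect_equal(silent$frequency_hz, 0)
})

test_that("sAP counts equal the crossing oracle on simulated firing", {
  sp <- make_presets()$type1
  sp$I_bg <- 60; sp$sigma_noise <- 15
  ss <- simulate_sweeps(sp, protocol_gap_free(duration = 5), seed = 21)
  v <- ss$sweeps[[1]]
  res <- detect_saps(v, ss$sample_rate)
  expect_gt(length(res$times_s), 0)
  expect_equal(length(res$times_s), oracle_spike_count(v, ss$sample_rate))
})

test_that("scaled-template detection meets the stated benchmark", {
  spec <- psc_trace_spec(rate = 2, amp_median = 15, amp_sigma = 0.25,
                         amp_min = 8, noise_sd = 1.5, duration = 60,
                         seed = 42)
  sim <- simulate_psc_trace(spec)
  det <- detect_pscs(sim$trace, sim$sample_rate)
  hits <- match_events(det$onset_time_s, sim$events$onset_time_s)
  recall <- mean(hits)
  precision <- mean(match_events(sim$events$onset_time_s,
                                 det$onset_time_s))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # matched amplitudes within 10% of ground truth (median)
  rel_err <- vapply(which(hits), function(i) {
    j <- which.min(abs(det$onset_time_s - sim$events$onset_time_s[i]))
    abs(det$amplitude_pA[j] - sim$events$amplitude_pA[i]) /
      sim$events$amplitude_pA[i]
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("the 5 pA amplitude cutoff rejects small events", {
  small <- simulate_psc_trace(psc_trace_spec(rate = 2, amp_median = 3,
                                             amp_sigma = 1e-6,
                                             noise_sd = 1.5,
                                             duration = 30, seed = 5))
  det <- detect_pscs(small$trace, small$sample_rate)
  expect_equal(nrow(det), 0)
})

test_that("pure noise yields a negligible false-event rate", {
  noise <- simulate_psc_trace(psc_trace_spec(rate = 0, noise_sd = 1.5,
                                             duration = 30, seed = 7))
  det <- detect_pscs(noise$trace, noise$sample_rate)
  expect_lt(nrow(det) / 30, 0.1)
})

test_that("detection is DC-translation invariant and criterion-monotone", {
  spec <- psc_trace_spec(rate = 3, amp_median = 12, noise_sd = 1.5,
                         duration = 10, seed = 13)
  sim <- simulate_psc_trace(spec)
  d0 <- detect_pscs(sim$trace, sim$sample_rate)
  d_shift <- detect_pscs(sim$trace - 55, sim$sample_rate)
  expect_equal(d_shift, d0)
  counts <- vapply(c(2.5, 3.5, 5, 8),
                   function(cr) nrow(detect_pscs(sim$trace,
                                                 sim$sample_rate,
                                                 criterion = cr)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("event statistics and degenerate inputs behave", {
  ev <- data.frame(amplitude_pA = c(10, 20))
  st <- event_stats(ev, 60)
  expect_equal(st$frequency_hz, 2 / 60)
  expect_equal(st$mean_amplitude_pA, 15)
  st120 <- event_stats(data.frame(amplitude_pA = rep(8, 120)), 60)
  expect_equal(st120$frequency_hz, 2)
  st0 <- event_stats(ev[0, , drop = FALSE], 10)
  expect_equal(st0$frequency_hz, 0)
  expect_true(is.na(st0$mean_amplitude_pA))
  expect_error(event_stats(ev, 0), class = "event_error")
  # template longer than the trace
  expect_error(detect_pscs(rnorm(100), 20000), class = "template_error")
})
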