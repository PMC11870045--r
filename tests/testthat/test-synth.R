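test_that("quiescent membrane settles to the closed-form resting potential", {
  sp <- neuron_spec(g_h = 0, sigma_noise = 0)
  ss <- simulate_sweeps(sp, protocol_gap_free(duration = 0.5), seed = 1)
  v_end <- tail(ss$sweeps[[1]], 1)
  expect_lt(abs(v_end - resting_potential(sp)), 0.5)
  expect_equal(nrow(ss$annotations$true_spikes[[1]]), 0)
})

test_that("subthreshold test pulse obeys the Ohmic closed form", {
  sp <- neuron_spec(g_L = 2.5, g_tonic_inh = 0.5, g_GIRK = 0.3,
                    g_h = 0, a_w = 0, g_BK = 0, sigma_noise = 0)
  ss <- simulate_sweeps(sp, protocol_test_pulse(n_repeats = 1), seed = 1)
  v <- ss$sweeps[[1]]
  fs <- ss$sample_rate
  base <- mean(v[1:(0.1 * fs)])
  # E_L/E_Cl/E_K differ, so the pulse deflection rides on a mixed rest;
  # the DELTA must be I / g_total
  dv <- min(v) - base
  expect_equal(dv, -10 / (2.5 + 0.5 + 0.3), tolerance = 0.02)
})

test_that("subthreshold steady-state deflection is linear in current", {
  sp <- neuron_spec(g_h = 0, a_w = 0, g_BK = 0, sigma_noise = 0)
  dvs <- vapply(c(-20, -10, 10, 20), function(amp) {
    pr <- protocol_test_pulse(test_amp = amp, test_dur = 0.3,
                              n_repeats = 1)
    v <- simulate_sweeps(sp, pr, seed = 1)$sweeps[[1]]
    fs <- 20000
    mean(v[(0.38 * fs):(0.4 * fs)]) - mean(v[1:(0.1 * fs)])
  }, numeric(1))
  slopes <- dvs / c(-20, -10, 10, 20)
  expect_lt(diff(range(slopes)) / mean(slopes), 0.02)
})

test_that("simulation is bit-identical for identical seeds and differs across seeds", {
  sp <- make_presets()$type3  # stochastic preset
  pr <- protocol_step_family(step_min = 50, step_max = 80, tail = 0.02)
  a <- simulate_sweeps(sp, pr, seed = 42)
  b <- simulate_sweeps(sp, pr, seed = 42)
  expect_identical(a$sweeps, b$sweeps)
  c <- simulate_sweeps(sp, pr, seed = 43)
  expect_false(identical(a$sweeps, c$sweeps))
})

test_that("pasted spikes carry exact waveform ground truth", {
  sp <- make_presets()$type1
  ss <- simulate_sweeps(sp, quick_steps(), seed = 1)
  truth <- ss$annotations$true_spikes
  k <- which(vapply(truth, nrow, integer(1)) >= 3)[1]
  tr <- truth[[k]]
  v <- ss$sweeps[[k]]
  fs <- ss$sample_rate
  peak_idx <- round(tr$peak_time_s * fs) + 1L
  expect_equal(v[peak_idx], tr$peak_V, tolerance = 1e-10)
  # onset sample holds the recorded threshold voltage
  onset_idx <- round(tr$onset_time_s * fs) + 1L
  expect_equal(v[onset_idx], tr$onset_V, tolerance = 1e-10)
})

test_that("a divergent membrane raises an integration error naming the sweep", {
  sp <- neuron_spec(g_L = 0.05, C_m = 5, V_T = 50, V_cut = 60,
                    Delta_T = 2, g_h = 0)
  pr <- protocol_sag_pulse(sag_amp = -500, n_repeats = 1)
  expect_error(simulate_sweeps(sp, pr, seed = 1),
               "diverged.*sweep 1", class = "integration_error")
})

test_that("presets reproduce the empirical type signatures and orderings", {
  coh <- fixture_cohort()
  by_type <- split(coh, coh$true_type)
  med <- function(ty, f) stats::median(by_type[[ty]][[f]], na.rm = TRUE)
  # tau ordering: bursting > adapting > irregular
  expect_gt(med("type2", "tau"), med("type1", "tau"))
  expect_gt(med("type1", "tau"), med("type3", "tau"))
  # rheobase ordering: irregular > adapting > bursting
  expect_gt(med("type3", "rheobase"), med("type1", "rheobase"))
  expect_gt(med("type1", "rheobase"), med("type2", "rheobase"))
  # input resistance ordering
  expect_gt(med("type2", "R_in"), med("type1", "R_in"))
  expect_gt(med("type1", "R_in"), med("type3", "R_in"))
  # firing-pattern flags
  expect_true(all(by_type$type2$burst_or_adaptive == "burst"))
  expect_true(all(by_type$type2$rebound))
  expect_true(all(by_type$type1$burst_or_adaptive == "adaptive"))
})

test_that("applying then reverting a drug condition restores the spec exactly", {
  sp <- make_presets()$type1
  for (cond in list("baclofen", "paxilline", "picrotoxin", "apv_dnqx",
                    c("picrotoxin", "paxilline", "baclofen"))) {
    restored <- revert_condition(apply_condition(sp, cond))
    expect_identical(restored, sp, label = paste(cond, collapse = "+"))
  }
  expect_error(drug_condition("caffeine"), "unknown",
               class = "condition_error")
})

test_that("synthetic PSC traces match their construction", {
  # rate 0: pure noise, empty truth
  s0 <- simulate_psc_trace(psc_trace_spec(rate = 0, noise_sd = 2,
                                          duration = 5, seed = 3))
  expect_equal(nrow(s0$events), 0)
  expect_equal(sd(s0$trace), 2, tolerance = 0.05)
  # Poisson count within 3 sigma of rate * duration
  s1 <- simulate_psc_trace(psc_trace_spec(rate = 2, duration = 60,
                                          seed = 9))
  expect_lt(abs(nrow(s1$events) - 120), 3 * sqrt(120))
  # isolated noiseless events hit their recorded amplitude exactly
  s2 <- simulate_psc_trace(psc_trace_spec(rate = 0.5, noise_sd = 0,
                                          duration = 20, seed = 5))
  x <- -s2$trace
  iso <- s2$events[c(diff(s2$events$onset_time_s) > 0.1, TRUE) &
                     c(TRUE, diff(s2$events$onset_time_s) > 0.1), ]
  for (i in seq_len(nrow(iso))) {
    j <- round(iso$onset_time_s[i] * 20000) + 1
    win <- x[j:min(length(x), j + 600)]
    expect_equal(max(win), iso$amplitude_pA[i], tolerance = 0.01)
  }
  expect_error(psc_trace_spec(tau_rise = 5, tau_decay = 2),
               class = "psc_error")
})
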