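fs <- 20000

test_that("spike detection follows the 0 mV overshoot criterion", {
  flat <- rep(-70, 2000)
  expect_length(detect_spikes(flat, fs), 0)
  # subthreshold hump peaking at -10 mV is not a spike
  hump <- -70 + 60 * exp(-((1:2000) - 1000)^2 / 1e4)
  expect_lt(max(hump), 0)
  expect_length(detect_spikes(hump, fs), 0)
  # pasted waveforms crossing 0 mV are counted once each, on the peak
  ss <- simulate_sweeps(make_presets()$type1, quick_steps(), seed = 2)
  truth <- ss$annotations$true_spikes
  for (k in seq_along(ss$sweeps)) {
    peaks <- detect_spikes(ss$sweeps[[k]], fs)
    expect_equal(length(peaks), nrow(truth[[k]]))
    if (length(peaks))
      expect_true(all(abs((peaks - 1) / fs - truth[[k]]$peak_time_s) <=
                        1 / fs))
  }
})

test_that("threshold detection matches the quadratic-ramp closed form", {
  # V(t) = -60 + 2.5 t^2 (t in ms): dV/dt = 5t, criterion 5 mV/ms at t = 1
  t_ms <- seq(0, 3, by = 1000 / fs / 1000 * 1000) / 1000
  t_ms <- (0:(0.003 * fs)) / fs * 1000
  v <- -60 + 2.5 * t_ms^2
  thr <- spike_threshold(v, peak_idx = length(v), sample_rate = fs)
  t_hit <- (thr$idx - 1) / fs * 1000
  expect_equal(t_hit, 1, tolerance = 0.06)   # within ~1 sample of t = 1 ms
  expect_equal(thr$V, -57.5, tolerance = 0.3)
})

test_that("an instantaneous voltage step is its own threshold onset", {
  v <- c(rep(-60, 100), seq(-55, 20, by = 5), rep(20, 20))  # 100 mV/ms
  pk <- 100 + which.max(v[101:136])
  thr <- spike_threshold(v, pk, fs)
  expect_equal(thr$idx, 100)
  # criterion never met in a slow ramp -> threshold error
  slow <- seq(-70, -50, length.out = 400)  # 1 mV/ms
  expect_error(spike_threshold(slow, 400, fs), class = "threshold_error")
})

test_that("pasted-waveform threshold recovers the generator onset", {
  ss <- simulate_sweeps(make_presets()$type1, quick_steps(), seed = 5)
  k <- which(vapply(ss$annotations$true_spikes, nrow, integer(1)) >= 2)[1]
  tr <- ss$annotations$true_spikes[[k]]
  tab <- sweep_spikes(ss$sweeps[[k]], fs)
  expect_equal(nrow(tab), nrow(tr))
  expect_true(all(abs(tab$threshold_V - tr$onset_V) <= 0.5))
  expect_true(all(abs(tab$threshold_time_ms / 1000 - tr$onset_time_s) <=
                    1 / fs + 1e-12))
})

test_that("triangular spike shape matches the analytic half-width", {
  # threshold -40, peak +20, symmetric 1 mV/sample flanks
  up <- seq(-40, 20, by = 1)
  down <- seq(19, -50, by = -1)
  v <- c(rep(-40, 200), up, down, rep(-50, 400))
  pk <- 200 + length(up)
  thr <- list(idx = 200L, V = -40)
  shp <- spike_shape(v, pk, thr, fs)
  expect_equal(shp$amplitude, 60)
  # half level -10: crossings interpolate exactly on the 1 mV/sample flanks
  hw_samples <- 30 + 29  # rising -10 -> peak is 30 samples; decay 29+1
  expect_equal(shp$half_width, 60 * 1000 / fs, tolerance = 0.02)
  # monotone decay never dipping below threshold: mAHP <= 0, unclamped
  v2 <- c(rep(-40, 200), up, seq(19, -35, by = -1), rep(-35, 400))
  shp2 <- spike_shape(v2, pk, thr, fs)
  expect_lte(shp2$mAHP, 0)
})

test_that("waveform ground truth is recovered within tolerance", {
  sp <- make_presets()$type1
  ss <- simulate_sweeps(sp, quick_steps(), seed = 8)
  shape <- sp$ap_shape
  ks <- which(vapply(ss$annotations$true_spikes, nrow, integer(1)) >= 2)
  for (k in ks[1:2]) {
    tr <- ss$annotations$true_spikes[[k]]
    tab <- sweep_spikes(ss$sweeps[[k]], fs)
    ok <- !is.na(tab$half_width)
    # half-width and amplitude within one sample period of ground truth
    expect_true(all(abs(tab$half_width[ok] - tr$half_width_ms[ok]) <=
                      1000 / fs))
    expect_true(all(abs(tab$amplitude - tr$amplitude) <= 1))
    # fAHP within 0.5 mV of the designed depth
    expect_true(all(abs(tab$fAHP[ok] - shape$ahp_depth) <= 0.5))
  }
})

test_that("excitability scalars follow their printed-count arithmetic", {
  # counts [0,0,1,4,12] at 10..50 pA -> rheobase 30 pA, max 24 Hz
  counts <- c(0, 0, 1, 4, 12)
  currents <- seq(10, 50, by = 10)
  rheo <- currents[which(counts > 0)[1]]
  expect_equal(rheo, 30)
  expect_equal(max(counts) / 0.5, 24)
  # amplitude-change formula
  expect_equal((54 - 60) / 60, -0.1)
})

test_that("extracted rheobase matches a fine-grid oracle within one step", {
  sp <- make_presets()$type1
  coarse <- excitability_scalars(
    simulate_sweeps(sp, quick_steps(), seed = 1))$rheobase
  # 1 pA brute-force search around the coarse estimate
  fine <- NA
  for (amp in seq(coarse - 10, coarse, by = 1)) {
    pr <- protocol_step_family(step_min = amp, step_max = amp + 10,
                               step_increment = 10, tail = 0.02)
    ss <- simulate_sweeps(sp, pr, seed = 1)
    if (nrow(ss$annotations$true_spikes[[1]]) > 0) { fine <- amp; break }
  }
  expect_false(is.na(fine))
  expect_lte(abs(coarse - fine), 10)
})

test_that("adding leak conductance never lowers rheobase", {
  base <- make_presets()$type1
  rheos <- vapply(c(0, 0.4, 0.8), function(extra) {
    sp <- base
    sp$g_tonic_inh <- sp$g_tonic_inh + extra
    excitability_scalars(simulate_sweeps(sp, quick_steps(),
                                         seed = 3))$rheobase
  }, numeric(1))
  expect_true(all(diff(rheos) >= 0))
})

test_that("passive properties recover the RC closed forms", {
  # R = 400 MOhm, C = 100 pF -> tau = 40 ms
  cell <- simulate_cell(neuron_spec(g_L = 2.5, C_m = 100, E_L = -60,
                                    g_h = 0, a_w = 0, g_BK = 0), seed = 1)
  pp <- passive_properties(cell$test, cell$sag)
  expect_equal(pp$R_in, 400, tolerance = 0.02)
  expect_equal(pp$tau, 40, tolerance = 0.05)
  expect_equal(pp$Cp, 100, tolerance = 0.07)
  expect_equal(pp$tau63, pp$tau, tolerance = 0.05)
  # pure RC: no sag mechanism -> negligible sag amplitude, no rebound
  expect_lt(pp$sag_amp, 0.5)
  expect_false(pp$rebound)
})

test_that("sag amplitude is the minimum-to-steady-state difference", {
  # V_min -85, V_steady -80 -> sag 5 mV; construct the trace directly
  fs2 <- 20000
  pr <- protocol_sag_pulse(n_repeats = 1)
  n <- round(0.8 * fs2)
  on <- round(0.1 * fs2) + 1; off <- round(0.6 * fs2)
  v <- rep(-70, n)
  v[on:off] <- -80
  dip <- on:(on + 400)
  v[dip] <- -85 + 5 * (seq_along(dip) - 1) / 400
  ss <- sweep_set(fs2, "voltage_mV", list(v), -200, protocol = pr)
  test_cell <- simulate_cell(neuron_spec(), seed = 1)
  pp <- passive_properties(test_cell$test, ss)
  expect_equal(pp$sag_amp, 5, tolerance = 0.01)
})

test_that("AHP depths and sag are invariant under voltage translation", {
  sp <- make_presets()$type1
  ss <- simulate_sweeps(sp, quick_steps(), seed = 4)
  k <- which(vapply(ss$annotations$true_spikes, nrow, integer(1)) >= 3)[1]
  v <- ss$sweeps[[k]]
  tab <- sweep_spikes(v, fs)
  # shifting the trace and the detection criterion's frame together:
  # differences (amplitude, AHP depth, half-width) must not move
  offset <- 7.5
  peaks2 <- detect_spikes(v + offset, fs, refractory_ms = 1)
  tab2 <- do.call(rbind, lapply(peaks2, function(pk) {
    thr <- spike_threshold(v + offset, pk, fs)
    as.data.frame(spike_shape(v + offset, pk, thr, fs))
  }))
  expect_equal(tab2$amplitude, tab$amplitude, tolerance = 1e-10)
  expect_equal(tab2$fAHP, tab$fAHP, tolerance = 1e-10)
  expect_equal(tab2$half_width, tab$half_width, tolerance = 1e-10)
})

test_that("assembled feature vectors are complete for healthy cells", {
  coh <- fixture_cohort()
  expect_true(all(feature_names() %in% names(coh)))
  numeric_feats <- setdiff(feature_names(),
                           c("rebound", "burst_or_adaptive"))
  miss_per_cell <- rowSums(is.na(coh[numeric_feats]))
  expect_true(all(miss_per_cell <= 4))
  # a non-spiking cell is excluded with a message
  dud <- neuron_spec(V_T = 100, V_cut = 120, g_h = 0)
  rec <- simulate_cell(dud, seed = 1,
                       protocol = protocol_step_family(step_max = 60,
                                                       tail = 0.02))
  row <- suppressWarnings(assemble_features(rec))
  expect_true(is.na(row$rheobase))
  expect_true(attr(row, "excluded"))
})
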