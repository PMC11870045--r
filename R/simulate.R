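#' Simulate current-clamp sweeps from a model neuron
#'
#' Integrates the adaptive exponential integrate-and-fire subthreshold
#' dynamics with fixed-step exponential-Euler updates at the protocol
#' sampling interval (0.05 ms at 20 kHz). Whenever the membrane reaches the
#' numerical trigger `V_cut`, the model spike is replaced by the neuron's
#' stereotyped action-potential waveform (linear rise to `peak`, linear fall
#' to `onset - ahp_depth`, exponential recovery towards `V_reset`, never
#' descending below the AHP floor), so that
#' peak time, threshold, amplitude, half-width and AHP depth of every spike
#' have exact, recorded ground truth. Adaptation, sag and BK gating continue
#' to integrate through the pasted waveform; the spike-triggered adaptation
#' and BK increments are applied at the trigger sample.
#'
#' @param spec a [neuron_spec()].
#' @param protocol a protocol from [protocol_step_family()] and friends.
#' @param condition a [drug_condition()] or character vector of condition
#'   names, applied to `spec` before simulation. Default `"control"`.
#' @param seed integer master seed; per-sweep noise streams are derived from
#'   it with [derive_seed()], so identical inputs give bit-identical output.
#' @return a [sweep_set()] of voltage sweeps (mV). `annotations` carries the
#'   applied spec, the condition name, and per-sweep ground truth: a list
#'   `true_spikes` of data frames with columns `onset_time_s`, `peak_time_s`,
#'   `onset_V`, `peak_V`, `amplitude`, `half_width_ms`, `ahp_depth`.
#' @export
simulate_sweeps <- function(spec, protocol, condition = "control", seed = 1L) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(protocol, "protocol"))
  if (!inherits(condition, "drug_condition"))
    condition <- drug_condition(condition)
  spec_c <- apply_condition(spec, condition)
  validate_neuron_spec(spec_c)
  dt_ms <- 1000 / protocol$sample_rate
  if (dt_ms > 0.05 + 1e-12)
    ephys_error("integration step must be <= 0.05 ms; raise sample_rate",
                "protocol_error")
  amps <- protocol_amplitudes(protocol)
  sweeps <- vector("list", length(amps))
  truth <- vector("list", length(amps))
  for (k in seq_along(amps)) {
    I <- protocol_current(protocol, amps[k])
    sim <- simulate_sweep_core(spec_c, I, dt_ms,
                               derive_seed(seed, k - 1L), sweep_index = k)
    sweeps[[k]] <- sim$V
    truth[[k]] <- sim$truth
  }
  sweep_set(sample_rate = protocol$sample_rate,
            channel_kind = "voltage_mV",
            sweeps = sweeps,
            step_amplitudes = amps,
            protocol = protocol,
            annotations = list(condition = paste(condition$name,
                                                 collapse = "+"),
                               spec = spec_c,
                               true_spikes = truth))
}

# stereotyped AP waveform sampled on the dt grid, starting one sample after
# the onset sample (whose value is V_on)
ap_waveform <- function(V_on, shape, V_reset, dt_ms) {
  n_r <- max(1L, as.integer(round(shape$rise / dt_ms)))
  n_f <- max(1L, as.integer(round(shape$fall / dt_ms)))
  n_a <- as.integer(round(6 / dt_ms))  # covers the 6 ms mAHP window
  V_min <- V_on - shape$ahp_depth
  rise <- V_on + seq_len(n_r) * (shape$peak - V_on) / n_r
  fall <- shape$peak - seq_len(n_f) * (shape$peak - V_min) / n_f
  # recovery never descends below the designed AHP floor, so ahp_depth is
  # exact ground truth even when V_reset sits below it
  rec_to <- max(V_reset, V_min)
  rec <- rec_to + (V_min - rec_to) * exp(-seq_len(n_a) * dt_ms /
                                           shape$ahp_tau)
  list(V = c(rise, fall, rec), n_r = n_r, n_f = n_f,
       half_width = analytic_half_width(V_on, shape))
}

# exact half-width of the piecewise-linear spike flanks (ms)
analytic_half_width <- function(V_on, shape) {
  A <- shape$peak - V_on
  shape$rise / 2 + shape$fall * (A / 2) / (A + shape$ahp_depth)
}

# one-sweep integrator; I is the injected current vector in pA.
# scalar model state lives in local variables: the loop runs once per
# 0.05 ms sample, so field lookups are hoisted out of it
simulate_sweep_core <- function(spec, I, dt_ms, noise_seed, sweep_index = 1L) {
  n <- length(I)
  noise <- ou_noise(n, spec$sigma_noise, spec$tau_noise, dt_ms, noise_seed)
  shp <- spec$ap_shape
  rho_h <- exp(-dt_ms / spec$tau_h)
  rho_w <- exp(-dt_ms / spec$tau_w)
  rho_bk <- exp(-dt_ms / spec$tau_BK)
  g_bk_t <- spec$phi_BK * spec$g_BK * spec$ca_scale
  g_fix <- spec$g_L + spec$g_tonic_inh + spec$g_GIRK + g_bk_t
  E_fix <- spec$g_L * spec$E_L + spec$g_tonic_inh * spec$E_Cl +
    (spec$g_GIRK + g_bk_t) * spec$E_K
  g_L <- spec$g_L; E_L <- spec$E_L; Delta_T <- spec$Delta_T
  V_T <- spec$V_T; V_cut <- spec$V_cut; V_reset <- spec$V_reset
  a_w <- spec$a_w; b_w <- spec$b_w
  g_h <- spec$g_h; E_h <- spec$E_h
  V_half_h <- spec$V_half_h; k_h <- spec$k_h
  g_BK_inc <- (1 - spec$phi_BK) * spec$g_BK * spec$ca_scale
  E_K <- spec$E_K
  I_bg <- spec$I_bg; C_m <- spec$C_m
  gLDT <- g_L * Delta_T
  V <- numeric(n)
  # tonically active cells (no subthreshold fixed point) start at reset
  v <- tryCatch(resting_potential(spec),
                spec_error = function(e) spec$V_reset)
  h <- 1 / (1 + exp((v - V_half_h) / k_h))
  w <- a_w * (v - E_L)
  gbk <- 0
  V[1] <- v
  onset_i <- integer(0); peak_i <- integer(0)
  onset_v <- numeric(0); hw <- numeric(0)
  i <- 2L
  while (i <= n) {
    h_inf <- 1 / (1 + exp((v - V_half_h) / k_h))
    h <- h_inf + (h - h_inf) * rho_h
    w_inf <- a_w * (v - E_L)
    w <- w_inf + (w - w_inf) * rho_w
    gbk <- gbk * rho_bk
    g_tot <- g_fix + g_h * h + gbk
    ex_arg <- (v - V_T) / Delta_T
    expo <- gLDT * exp(if (ex_arg > 16) 16 else ex_arg)
    num <- E_fix + g_h * h * E_h + gbk * E_K +
      expo + I[i] + noise[i] + I_bg - w
    E_eff <- num / g_tot
    v_new <- E_eff + (v - E_eff) * exp(-g_tot * dt_ms / C_m)
    if (v_new >= V_cut) {
      # spike: paste the stereotyped waveform from the onset sample i-1
      wf <- ap_waveform(v, shp, V_reset, dt_ms)
      j_end <- min(n, (i - 1L) + length(wf$V))
      idx <- seq_len(j_end - (i - 1L))
      V[(i - 1L) + idx] <- wf$V[idx]
      pk <- (i - 1L) + wf$n_r
      if (pk <= n) {
        onset_i <- c(onset_i, i - 1L); peak_i <- c(peak_i, pk)
        onset_v <- c(onset_v, v); hw <- c(hw, wf$half_width)
      }
      w <- w + b_w
      gbk <- gbk + g_BK_inc
      # gating keeps integrating through the pasted waveform
      nj <- length(idx)
      wfv <- V[(i - 1L) + idx]
      h_infs <- 1 / (1 + exp((wfv - V_half_h) / k_h))
      for (j in seq_len(nj)) {
        h <- h_infs[j] + (h - h_infs[j]) * rho_h
        w_inf <- a_w * (wfv[j] - E_L)
        w <- w_inf + (w - w_inf) * rho_w
      }
      gbk <- gbk * rho_bk^nj
      v <- V[j_end]
      i <- j_end + 1L
      next
    }
    if (v_new < -150 || v_new > 80)
      ephys_error(sprintf(
        "integration diverged (V = %.1f mV) in sweep %d at sample %d",
        v_new, sweep_index, i), "integration_error")
    v <- v_new
    V[i] <- v
    i <- i + 1L
  }
  dt_s <- dt_ms / 1000
  truth <- data.frame(onset_time_s = (onset_i - 1L) * dt_s,
                      peak_time_s = (peak_i - 1L) * dt_s,
                      onset_V = onset_v,
                      peak_V = rep(shp$peak, length(onset_i)),
                      amplitude = shp$peak - onset_v,
                      half_width_ms = hw,
                      ahp_depth = rep(shp$ahp_depth, length(onset_i)))
  list(V = V, truth = truth)
}
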