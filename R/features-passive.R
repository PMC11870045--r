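#' Passive membrane properties from test and sag pulses
#'
#' From the -10 pA / 100 ms test pulse: resting potential `V_m` (mean of
#' the pre-pulse baseline), input resistance `R_in` (steady-state voltage
#' deflection over injected current), membrane time constant `tau` (single
#' exponential fitted to the pulse-onset transient, cross-checked against
#' the 63% criterion) and capacitance `Cp = tau / R_in`. Because the pulse
#' may be short relative to tau, the steady-state deflection is taken from
#' the fitted exponential's asymptote rather than the raw trace tail.
#'
#' From the -200 pA / 500 ms sag pulse: sag amplitude (positive magnitude
#' of minimum minus steady-state voltage, steady state being the mean of
#' the last 50 ms of the pulse) and the rebound flag (any overshooting
#' spike within 100 ms after pulse offset).
#'
#' @param test_set a single-sweep voltage [sweep_set()] from
#'   [protocol_test_pulse()].
#' @param sag_set a single-sweep voltage [sweep_set()] from
#'   [protocol_sag_pulse()]; may be `NULL`, then sag/rebound are `NA`.
#' @param rmse_frac tau is reported `NA` with a warning when the
#'   exponential fit RMSE exceeds this fraction of the deflection.
#' @return list with `R_in` (MOhm), `tau` (ms), `Cp` (pF), `V_m` (mV),
#'   `sag_amp` (mV), `rebound` (logical), and `tau63` (the 63% criterion
#'   cross-check, ms).
#' @export
passive_properties <- function(test_set, sag_set = NULL, rmse_frac = 0.2) {
  stopifnot(inherits(test_set, "sweep_set"),
            test_set$channel_kind == "voltage_mV")
  fs <- test_set$sample_rate
  proto <- test_set$protocol
  if (is.null(proto))
    ephys_error("test_set must carry its protocol", "feature_error")
  on <- round(proto$step_start * fs) + 1L
  off <- round((proto$step_start + proto$step_dur) * fs)
  amp <- abs(if (!is.null(proto$test_amp)) proto$test_amp else
               test_set$step_amplitudes[1])
  # repeats of the small test pulse are averaged for noise suppression
  v <- Reduce(`+`, test_set$sweeps) / length(test_set$sweeps)
  base_lo <- max(1L, on - as.integer(round(0.05 * fs)))
  V_m <- mean(v[base_lo:(on - 1L)])
  # single-exponential fit to the onset transient
  seg <- v[on:off]
  t_ms <- (seq_along(seg) - 1L) * 1000 / fs
  V0 <- seg[1]
  Vss0 <- mean(seg[t_ms >= max(t_ms) * 0.8])
  dV0 <- Vss0 - V0
  tau0 <- t_ms[which(abs(seg - V0) >= 0.63 * abs(dV0))[1]]
  if (is.na(tau0) || tau0 <= 0) tau0 <- max(t_ms) / 5
  # box constraints keep the asymptote near the observed tail and stop
  # tau from trading off against correlated noise in short pulses
  slack <- 0.35 * abs(dV0) + 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ Vss + (V0f - Vss) * exp(-t_ms / tau),
                      start = list(Vss = Vss0, V0f = V0, tau = tau0),
                      lower = c(Vss = min(Vss0 - slack, Vss0 + slack),
                                V0f = V0 - 2, tau = 0.5),
                      upper = c(Vss = max(Vss0 - slack, Vss0 + slack),
                                V0f = V0 + 2, tau = 150),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tau <- tau63 <- NA_real_
  Vss <- Vss0
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    tau <- unname(cf["tau"])
    Vss <- unname(cf["Vss"])
    rmse <- sqrt(mean(stats::resid(fit)^2))
    # the RMSE guard is relative to the OBSERVED deflection and the fit
    # must be sane: a runaway asymptote / time constant means the
    # transient was not exponential
    if (!is.finite(tau) || tau <= 0 || tau > 2 * max(t_ms) ||
        abs(Vss - Vss0) > abs(dV0) + 2 ||
        rmse > rmse_frac * max(abs(dV0), 1e-9)) {
      warning("noisy or non-exponential transient; tau set to NA")
      tau <- NA_real_
      Vss <- Vss0
    } else {
      # 63% criterion on the fitted curve as a cross-check
      tau63 <- t_ms[which(abs(seg - V0) >= 0.63 * abs(Vss - V0))[1]]
    }
  } else {
    warning("exponential fit failed; tau set to NA")
  }
  R_in <- abs(Vss - V_m) / amp * 1000  # mV/pA = GOhm -> MOhm
  Cp <- if (is.na(tau)) NA_real_ else tau / R_in * 1000  # ms/MOhm -> pF
  sag_amp <- NA_real_
  rebound <- NA
  if (!is.null(sag_set)) {
    sp <- sag_set$protocol
    fs2 <- sag_set$sample_rate
    on2 <- round(sp$step_start * fs2) + 1L
    off2 <- round((sp$step_start + sp$step_dur) * fs2)
    vs <- Reduce(`+`, sag_set$sweeps) / length(sag_set$sweeps)
    v_min <- min(vs[on2:off2])
    v_steady <- mean(vs[(off2 - as.integer(round(0.05 * fs2))):off2])
    sag_amp <- v_steady - v_min
    # rebound is per-sweep: averaging would wash spikes out
    reb_end <- min(length(vs), off2 + as.integer(round(0.1 * fs2)))
    rebound <- any(vapply(sag_set$sweeps, function(s)
      length(detect_spikes(s, fs2, window = c(off2 + 1L, reb_end))) > 0,
      logical(1)))
  }
  list(R_in = R_in, tau = tau, Cp = Cp, V_m = V_m, sag_amp = sag_amp,
       rebound = rebound, tau63 = tau63)
}
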