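#' Parametric model neuron specification
#'
#' Builds the generative model used by [simulate_sweeps()]: adaptive
#' exponential integrate-and-fire subthreshold dynamics plus a stereotyped
#' pasted action-potential waveform, with optional sag (h-type), BK-like,
#' tonic chloride and GIRK conductances, and Ornstein-Uhlenbeck current
#' noise. Every parameter is ground truth that the feature-extraction
#' modules can be validated against.
#'
#' The BK-like conductance has two components, both scaled by `ca_scale`
#' (a stand-in for extracellular calcium availability in \[0, 1\]): a tonic
#' fraction `phi_BK * g_BK` active at rest, which shifts rheobase, and a
#' spike-triggered increment `(1 - phi_BK) * g_BK` decaying with `tau_BK`,
#' which limits sustained firing.
#'
#' @param C_m membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param Delta_T spike slope factor (mV), > 0.
#' @param V_T exponential threshold (mV).
#' @param V_reset post-spike reset target (mV).
#' @param V_cut numerical spike trigger (mV); must exceed `V_reset`.
#' @param a_w subthreshold adaptation conductance (nS).
#' @param b_w spike-triggered adaptation increment (pA).
#' @param tau_w adaptation time constant (ms).
#' @param g_h sag (h-type) conductance (nS).
#' @param E_h sag reversal (mV).
#' @param V_half_h,k_h sag activation sigmoid midpoint and slope (mV);
#'   activation = 1/(1 + exp((V - V_half_h)/k_h)), increasing with
#'   hyperpolarization.
#' @param tau_h sag activation time constant (ms).
#' @param g_BK BK-like K conductance scale (nS).
#' @param phi_BK tonically active fraction of `g_BK` in \[0, 1\].
#' @param tau_BK decay of the spike-triggered BK component (ms).
#' @param E_K potassium reversal (mV).
#' @param ca_scale extracellular-calcium factor in \[0, 1\] multiplying the
#'   whole BK conductance.
#' @param g_tonic_inh tonic chloride (GABAa-like) conductance (nS).
#' @param E_Cl chloride reversal (mV).
#' @param g_GIRK added K leak (nS); nonzero in GABAb-agonist states.
#' @param I_bg standing background depolarizing current (pA), a lumped
#'   stand-in for net spontaneous synaptic drive in gap-free protocols.
#' @param sigma_noise OU current-noise stationary SD (pA).
#' @param tau_noise OU correlation time (ms).
#' @param ap_shape list with the stereotyped spike waveform parameters:
#'   `peak` (mV), `rise` (ms), `fall` (ms), `ahp_depth` (mV, depth below the
#'   spike onset voltage), `ahp_tau` (ms, recovery towards `V_reset`).
#' @return an object of class `neuron_spec`.
#' @seealso [make_presets()], [drug_condition()], [simulate_sweeps()]
#' @export
neuron_spec <- function(C_m = 80, g_L = 2.5, E_L = -70, Delta_T = 2,
                        V_T = -45, V_reset = -55, V_cut = -42,
                        a_w = 0, b_w = 0, tau_w = 100,
                        g_h = 0, E_h = -30, V_half_h = -80, k_h = 6,
                        tau_h = 100,
                        g_BK = 0, phi_BK = 0.3, tau_BK = 60, E_K = -90,
                        ca_scale = 1,
                        g_tonic_inh = 0, E_Cl = -75, g_GIRK = 0,
                        I_bg = 0, sigma_noise = 0, tau_noise = 5,
                        ap_shape = list(peak = 30, rise = 0.25, fall = 0.75,
                                        ahp_depth = 14, ahp_tau = 3)) {
  spec <- list(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T,
               V_T = V_T, V_reset = V_reset, V_cut = V_cut,
               a_w = a_w, b_w = b_w, tau_w = tau_w,
               g_h = g_h, E_h = E_h, V_half_h = V_half_h, k_h = k_h,
               tau_h = tau_h,
               g_BK = g_BK, phi_BK = phi_BK, tau_BK = tau_BK, E_K = E_K,
               ca_scale = ca_scale,
               g_tonic_inh = g_tonic_inh, E_Cl = E_Cl, g_GIRK = g_GIRK,
               I_bg = I_bg, sigma_noise = sigma_noise, tau_noise = tau_noise,
               ap_shape = ap_shape)
  class(spec) <- "neuron_spec"
  validate_neuron_spec(spec)
  spec
}

validate_neuron_spec <- function(spec) {
  with(spec, {
    if (any(c(C_m, g_L, a_w, g_h, g_BK, g_tonic_inh, g_GIRK) < 0))
      ephys_error("conductances and capacitance must be >= 0", "spec_error")
    if (Delta_T <= 0) ephys_error("Delta_T must be > 0", "spec_error")
    if (ca_scale < 0 || ca_scale > 1)
      ephys_error("ca_scale must lie in [0, 1]", "spec_error")
    if (phi_BK < 0 || phi_BK > 1)
      ephys_error("phi_BK must lie in [0, 1]", "spec_error")
    if (V_reset >= V_cut)
      ephys_error("V_reset must be below V_cut", "spec_error")
    if (any(c(tau_w, tau_h, tau_BK, tau_noise) <= 0))
      ephys_error("all time constants must be > 0", "spec_error")
    if (sigma_noise < 0)
      ephys_error("sigma_noise must be >= 0", "spec_error")
    shp <- ap_shape
    if (!all(c("peak", "rise", "fall", "ahp_depth", "ahp_tau") %in% names(shp)))
      ephys_error("ap_shape must name peak, rise, fall, ahp_depth, ahp_tau",
                  "spec_error")
    if (shp$rise <= 0 || shp$fall <= 0 || shp$ahp_tau <= 0)
      ephys_error("ap_shape time parameters must be > 0", "spec_error")
  })
  invisible(spec)
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat("<neuron_spec>\n")
  cat(sprintf("  passive: C_m %.1f pF, g_L %.3f nS, E_L %.1f mV (tau %.1f ms)\n",
              x$C_m, x$g_L, x$E_L, x$C_m / x$g_L))
  cat(sprintf("  spike:   V_T %.1f mV, Delta_T %.1f mV, reset %.1f mV\n",
              x$V_T, x$Delta_T, x$V_reset))
  cat(sprintf("  adapt:   a_w %.2f nS, b_w %.1f pA, tau_w %.0f ms\n",
              x$a_w, x$b_w, x$tau_w))
  cat(sprintf("  sag:     g_h %.2f nS; BK: g_BK %.2f nS (phi %.2f, ca %.2f); GIRK %.2f nS; tonic inh %.2f nS\n",
              x$g_h, x$g_BK, x$phi_BK, x$ca_scale, x$g_GIRK, x$g_tonic_inh))
  cat(sprintf("  noise:   sigma %.1f pA (tau %.0f ms); I_bg %.1f pA\n",
              x$sigma_noise, x$tau_noise, x$I_bg))
  invisible(x)
}

#' Closed-form resting potential of a model neuron
#'
#' Solves the subthreshold steady-state current balance (including the
#' exponential term, steady sag activation and steady subthreshold
#' adaptation) for the fixed point the membrane settles to at zero injected
#' current. With a single Ohmic leak this reduces to the weighted mean of
#' the conductance reversal potentials.
#'
#' @param spec a [neuron_spec()].
#' @param I extra constant injected current (pA), default 0.
#' @return resting membrane potential (mV).
#' @export
resting_potential <- function(spec, I = 0) {
  f <- function(V) steady_current(spec, V) + I
  # the balance typically has a stable root (current turning outward) and,
  # past the exponential threshold, an unstable one; bracket the stable
  # root on a grid instead of assuming a sign change at the extremes
  grid <- seq(-120, spec$V_cut - 0.5, by = 0.25)
  fv <- vapply(grid, f, numeric(1))
  i <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)[1]
  if (is.na(i))
    ephys_error("no stable subthreshold resting potential (cell fires tonically)",
                "spec_error")
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-10)$root
}

# net subthreshold membrane current (pA) at steady state, positive = inward
steady_current <- function(spec, V) {
  h_inf <- 1 / (1 + exp((V - spec$V_half_h) / spec$k_h))
  expo <- spec$g_L * spec$Delta_T * exp((V - spec$V_T) / spec$Delta_T)
  -spec$g_L * (V - spec$E_L) + expo -
    spec$a_w * (V - spec$E_L) -
    spec$g_h * h_inf * (V - spec$E_h) -
    spec$phi_BK * spec$g_BK * spec$ca_scale * (V - spec$E_K) -
    spec$g_tonic_inh * (V - spec$E_Cl) -
    spec$g_GIRK * (V - spec$E_K) +
    spec$I_bg
}
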