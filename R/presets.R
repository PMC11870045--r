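#' Model-neuron presets for the three electrophysiological types
#'
#' Three calibrated specifications reproducing the qualitative signatures
#' of the interneuron types recovered by clustering cortical VIP-cell
#' recordings:
#' \describe{
#'   \item{type1}{continuously adapting firing: moderate input resistance
#'     and rheobase, strong spike-triggered adaptation, BK conductance
#'     present (so BK-blocker and GABAb-agonist conditions shift its
#'     excitability).}
#'   \item{type2}{bursting: highest input resistance and membrane time
#'     constant, lowest rheobase, depolarized reset producing an initial
#'     doublet, prominent sag conductance giving a rebound spike.}
#'   \item{type3}{irregular: lowest input resistance and time constant,
#'     highest rheobase, strong OU current noise making firing irregular.}
#' }
#' The presets preserve the empirical orderings
#' tau: type2 > type1 > type3, input resistance: type2 > type1 > type3,
#' rheobase: type3 > type1 > type2.
#'
#' @return named list of [neuron_spec()] objects.
#' @export
make_presets <- function() {
  list(
    type1 = neuron_spec(
      C_m = 60, g_L = 1.7, E_L = -59.5, V_T = -45, V_reset = -58,
      V_cut = -43,
      a_w = 0.3, b_w = 2, tau_w = 800,
      g_h = 0.4, E_h = -30, V_half_h = -82, k_h = 6, tau_h = 40,
      g_BK = 0.45, phi_BK = 0.65, tau_BK = 300,
      g_tonic_inh = 0.25, sigma_noise = 0),
    type2 = neuron_spec(
      C_m = 55, g_L = 0.8, E_L = -58.5, V_T = -46, V_reset = -47.5,
      V_cut = -44,
      a_w = 0.05, b_w = 55, tau_w = 180,
      g_h = 3, E_h = -20, V_half_h = -82, k_h = 4, tau_h = 100,
      g_BK = 0.4, phi_BK = 0.65, tau_BK = 300,
      g_tonic_inh = 0.1, sigma_noise = 0),
    type3 = neuron_spec(
      C_m = 45, g_L = 2.6, E_L = -61.5, V_T = -42, V_reset = -56,
      V_cut = -40,
      a_w = 0.1, b_w = 3, tau_w = 400,
      g_h = 0.3, E_h = -30, V_half_h = -82, k_h = 6, tau_h = 40,
      g_BK = 0.5, phi_BK = 0.65, tau_BK = 300,
      g_tonic_inh = 0.3, sigma_noise = 10, tau_noise = 5))
}

#' Simulate one cell's full recording session
#'
#' Runs the three current-clamp protocols a cell needs for the 18-feature
#' vector: the depolarizing step family, the -200 pA sag/rebound pulse and
#' the -10 pA test pulse.
#'
#' @param spec a [neuron_spec()].
#' @param seed integer master seed.
#' @param condition [drug_condition()] or condition name(s).
#' @param protocol optional step-family protocol override.
#' @return list with sweep sets `steps`, `sag`, `test`.
#' @export
simulate_cell <- function(spec, seed = 1L, condition = "control",
                          protocol = protocol_step_family()) {
  list(steps = simulate_sweeps(spec, protocol, condition, seed),
       sag = simulate_sweeps(spec, protocol_sag_pulse(
         sample_rate = protocol$sample_rate), condition,
         derive_seed(seed, 101L)),
       test = simulate_sweeps(spec, protocol_test_pulse(
         sample_rate = protocol$sample_rate), condition,
         derive_seed(seed, 102L)))
}
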