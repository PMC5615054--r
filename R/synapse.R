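#' Synapse state constructor and event/decay/current operations
#'
#' A synapse carries an AMPA and an NMDA conductance and a weight. A
#' presynaptic spike raises both conductances instantaneously by
#' `w * g_max` (the NMDA jump optionally scales with the weight, see
#' [synapse_params()]); between spikes each conductance decays
#' exponentially with its own time constant (the exact decay factor
#' `exp(-dt/tau)` is applied per step). The synaptic current at local
#' voltage `u` is `-(g_ampa (u - E_AMPA) + g_nmda B(u) (u - E_NMDA))`,
#' positive into the compartment when `u` is below the reversal potentials,
#' and multiplied by the distal gain when the synapse sits on a distal
#' compartment. These are the same operations the simulation engine applies
#' in vectorised form.
#'
#' @param w Synaptic weight.
#' @param g_ampa,g_nmda Instantaneous conductances (nS).
#' @param is_distal Does the synapse sit on a distal compartment?
#' @return `synapse_state()` returns a list of class `"synapse_state"`;
#'   `on_presynaptic_spike()` and `decay_conductances()` return the updated
#'   state; `synaptic_current()` returns a current in pA.
#' @export
#' @examples
#' p <- synapse_params()
#' s <- synapse_state(w = 0.5)
#' s <- on_presynaptic_spike(s, p) # +50 nS AMPA, +25 nS NMDA
#' synaptic_current(s, u = -69, p)
synapse_state <- function(w = 1, g_ampa = 0, g_nmda = 0, is_distal = FALSE) {
  stopifnot(g_ampa >= 0, g_nmda >= 0)
  structure(
    list(
      w = w, g_ampa = g_ampa, g_nmda = g_nmda,
      is_distal = isTRUE(is_distal)
    ),
    class = "synapse_state"
  )
}

#' @rdname synapse_state
#' @param state A `synapse_state`.
#' @param params A [synapse_params()] object.
#' @param n_spikes Number of simultaneous presynaptic spikes (jumps add).
#' @export
on_presynaptic_spike <- function(state, params, n_spikes = 1) {
  state$g_ampa <- state$g_ampa + n_spikes * state$w * params$g_ampa_max
  state$g_nmda <- state$g_nmda + n_spikes *
    (if (params$nmda_scales_with_w) state$w else 1) * params$g_nmda
  state
}

#' @rdname synapse_state
#' @param dt Step (ms).
#' @export
decay_conductances <- function(state, dt, params) {
  state$g_ampa <- state$g_ampa * exp(-dt / params$tau_ampa)
  state$g_nmda <- state$g_nmda * exp(-dt / params$tau_nmda)
  state
}

#' @rdname synapse_state
#' @param u Local membrane voltage (mV).
#' @export
synaptic_current <- function(state, u, params) {
  i <- -(state$g_ampa * (u - params$e_ampa) +
    state$g_nmda * mg_block(u) * (u - params$e_nmda))
  if (state$is_distal) i <- i * params$distal_gain
  i
}
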