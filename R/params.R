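#' Reduced-neuron biophysical parameters
#'
#' Parameter set for the reduced multicompartment neuron: an exponential
#' integrate-and-fire soma with an adaptive threshold, electrically coupled to
#' `n_dendrites` dendrites of two point compartments each (proximal, distal).
#' Units follow the conventions used throughout the package: time in ms,
#' voltage in mV, capacitance in pF, conductance in nS, current in pA.
#'
#' The soma-dendrite and proximal-distal couplings are rectified: each
#' direction of current flow uses its own conductance, mimicking the
#' asymmetric efficiency of forward (soma to dendrite) versus backward
#' (dendrite to soma) propagation. Somatic spikes and their back-propagation
#' into the dendrites are modelled as brief voltage holds rather than by
#' axial current flow (see [axial_currents()] for the convention).
#'
#' @param dt Integration time step (ms).
#' @param c_m Membrane capacitance per compartment (pF).
#' @param g_l Leak conductance (nS).
#' @param e_l Resting potential (mV).
#' @param delta_t Slope factor of the somatic exponential current (mV).
#' @param v_t_rest,v_t_max Rest and post-spike values of the adaptive
#'   threshold (mV).
#' @param tau_v_t Adaptive-threshold relaxation time constant (ms).
#' @param theta_spike Somatic spike detection threshold (mV).
#' @param spike_width Duration of the somatic voltage hold after a spike (ms).
#' @param v_spike_soma Somatic hold voltage during a spike (mV).
#' @param v_reset Somatic voltage after the spike hold ends (mV).
#' @param v_bap_prox,v_bap_dist Dendritic hold voltages during the
#'   back-propagating action potential (mV).
#' @param bap_delay Delay of the dendritic hold relative to spike onset (ms).
#'   Realised on the step grid as the first boundary at or after this value.
#' @param g_soma_from_prox Conductance through which the soma receives
#'   current from a more depolarised proximal compartment (nS).
#' @param g_prox_from_soma_backward,g_prox_from_soma_forward Conductances
#'   governing the proximal compartment's coupling to the soma when the
#'   proximal side is higher (backward, 1250 nS) or the soma is higher
#'   (forward, 2500 nS).
#' @param g_prox_dist_backward,g_prox_dist_forward Same for the
#'   proximal-distal pair (backward 225 nS, forward 1500 nS).
#' @param g_dist_prox_forward,g_dist_prox_backward Conductances seen from the
#'   distal side: loss when the distal compartment leads (1500 nS), gain when
#'   it trails (225 nS).
#' @param n_dendrites Number of dendrites per neuron.
#'
#' @return A named list of class `"neuron_params"`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$c_m / p$g_l # somatic membrane time constant, ms
neuron_params <- function(dt = 0.25,
                          c_m = 281,
                          g_l = 40,
                          e_l = -69,
                          delta_t = 2,
                          v_t_rest = -50.4,
                          v_t_max = -30.4,
                          tau_v_t = 50,
                          theta_spike = 20,
                          spike_width = 1,
                          v_spike_soma = 30,
                          v_reset = -55,
                          v_bap_prox = 10,
                          v_bap_dist = -3,
                          bap_delay = 0.3,
                          g_soma_from_prox = 50,
                          g_prox_from_soma_backward = 1250,
                          g_prox_from_soma_forward = 2500,
                          g_prox_dist_backward = 225,
                          g_prox_dist_forward = 1500,
                          g_dist_prox_forward = 1500,
                          g_dist_prox_backward = 225,
                          n_dendrites = 15) {
  p <- list(
    dt = dt, c_m = c_m, g_l = g_l, e_l = e_l, delta_t = delta_t,
    v_t_rest = v_t_rest, v_t_max = v_t_max, tau_v_t = tau_v_t,
    theta_spike = theta_spike, spike_width = spike_width,
    v_spike_soma = v_spike_soma, v_reset = v_reset,
    v_bap_prox = v_bap_prox, v_bap_dist = v_bap_dist, bap_delay = bap_delay,
    g_soma_from_prox = g_soma_from_prox,
    g_prox_from_soma_backward = g_prox_from_soma_backward,
    g_prox_from_soma_forward = g_prox_from_soma_forward,
    g_prox_dist_backward = g_prox_dist_backward,
    g_prox_dist_forward = g_prox_dist_forward,
    g_dist_prox_forward = g_dist_prox_forward,
    g_dist_prox_backward = g_dist_prox_backward,
    n_dendrites = as.integer(n_dendrites)
  )
  pos <- c(
    "dt", "c_m", "g_l", "delta_t", "tau_v_t", "spike_width",
    "g_soma_from_prox", "g_prox_from_soma_backward",
    "g_prox_from_soma_forward", "g_prox_dist_backward",
    "g_prox_dist_forward", "g_dist_prox_forward", "g_dist_prox_backward"
  )
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("neuron_params: `", nm, "` must be strictly positive", call. = FALSE)
    }
  }
  if (p$dt >= min(p$tau_v_t, p$spike_width)) {
    stop("neuron_params: `dt` must be smaller than all time constants",
      call. = FALSE
    )
  }
  if (p$v_reset >= p$theta_spike) {
    stop("neuron_params: `v_reset` must lie below `theta_spike`",
      call. = FALSE
    )
  }
  if (p$n_dendrites < 1) {
    stop("neuron_params: need at least one dendrite", call. = FALSE)
  }
  structure(p, class = "neuron_params")
}

#' Coloured-noise (Ornstein-Uhlenbeck) current parameters
#'
#' The somatic noise current is an Ornstein-Uhlenbeck process parameterised by
#' its stationary mean and standard deviation and a correlation time constant.
#' Two equivalent formulations are supported: `"main_text"` drives a
#' dimensionless filtered state `s(t)` and reads the current as
#' `sqrt(2 tau) * s * sd + mean`, while `"fig5"` integrates the current
#' itself. Both are discretised with the exact Ornstein-Uhlenbeck transition,
#' so the stationary moments hold at any step size.
#'
#' @param mean Stationary mean current (pA).
#' @param sd Stationary standard deviation (pA).
#' @param tau Correlation time constant (ms).
#' @param form Process formulation, `"main_text"` or `"fig5"`.
#' @return A named list of class `"noise_params"`.
#' @export
noise_params <- function(mean = 0, sd = 0, tau = 20,
                         form = c("main_text", "fig5")) {
  form <- match.arg(form)
  if (!is.finite(sd) || sd < 0) {
    stop("noise_params: `sd` must be non-negative", call. = FALSE)
  }
  if (!is.finite(tau) || tau <= 0) {
    stop("noise_params: `tau` must be strictly positive", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, tau = tau, form = form),
    class = "noise_params"
  )
}

#' Conductance-based AMPA/NMDA synapse parameters
#'
#' A presynaptic spike raises both conductances instantaneously by
#' `w * g_max`; each then decays exponentially with its own time constant.
#' The NMDA current is additionally gated by the voltage-dependent magnesium
#' block [mg_block()]. Synaptic currents at distal compartments are scaled by
#' `distal_gain` to mimic their higher input resistance.
#'
#' Only the AMPA maximal conductance is subject to plasticity of the weight
#' in the sense that `g_ampa_max` is the plastic arm of the synapse; whether
#' the NMDA conductance jump also scales with the instantaneous weight is
#' controlled by `nmda_scales_with_w` (default `TRUE`, following the shared
#' conductance-jump rule).
#'
#' @param preset `"reduced"` (point-neuron values: 100/50 nS) or `"detailed"`
#'   (morphological-model values: 1.5/1.5 nS). Individual arguments override
#'   the preset.
#' @param tau_ampa,tau_nmda Decay time constants (ms).
#' @param e_ampa,e_nmda Reversal potentials (mV).
#' @param g_ampa_max Maximal AMPA conductance at weight 1 (nS).
#' @param g_nmda NMDA conductance scale (nS).
#' @param distal_gain Multiplier on synaptic currents at distal compartments.
#' @param nmda_scales_with_w Should the NMDA conductance jump scale with the
#'   current weight?
#' @return A named list of class `"synapse_params"`.
#' @export
synapse_params <- function(preset = c("reduced", "detailed"),
                           tau_ampa = 2, tau_nmda = 50,
                           e_ampa = 0, e_nmda = 0,
                           g_ampa_max = NULL, g_nmda = NULL,
                           distal_gain = 2.5,
                           nmda_scales_with_w = TRUE) {
  preset <- match.arg(preset)
  if (is.null(g_ampa_max)) g_ampa_max <- if (preset == "reduced") 100 else 1.5
  if (is.null(g_nmda)) g_nmda <- if (preset == "reduced") 50 else 1.5
  stopifnot(tau_ampa > 0, tau_nmda > 0, g_ampa_max >= 0, g_nmda >= 0)
  structure(
    list(
      preset = preset, tau_ampa = tau_ampa, tau_nmda = tau_nmda,
      e_ampa = e_ampa, e_nmda = e_nmda,
      g_ampa_max = g_ampa_max, g_nmda = g_nmda,
      distal_gain = distal_gain,
      nmda_scales_with_w = isTRUE(nmda_scales_with_w)
    ),
    class = "synapse_params"
  )
}

#' Voltage-dependent plasticity-rule parameters
#'
#' Parameters of the local voltage-based spike-timing rule. Depression is
#' triggered per presynaptic spike when a slow low-pass filter of the local
#' dendritic voltage exceeds `theta_minus`; potentiation integrates the
#' product of a presynaptic spike trace, the instantaneous voltage above
#' `theta_plus` and a second filtered voltage above `theta_minus`. Weights are
#' hard-clipped to `[w_min, w_max]`.
#'
#' Two filter variants exist. `"reduced_delay"` (the point-neuron rule) feeds
#' the filters with the voltage delayed by `eps` and additionally detects
#' NMDA-spike plateaus: when the local voltage has been above `theta_plus`
#' continuously for longer than a spike width (checked against the value
#' `dltp_lookback` ms earlier), the potentiation amplitude is multiplied by
#' `dltp_scale`. `"detailed_u1"` (the morphological-model rule) introduces the
#' delay through an extra first-order filter with time constant `tau_1` and
#' applies no plateau gating.
#'
#' @param preset `"reduced"` or `"detailed"`; individual arguments override.
#' @param a_ltd Depression amplitude (1/mV, applied per presynaptic spike).
#' @param a_ltp Potentiation amplitude (1/mV^2 per ms).
#' @param theta_minus Depolarisation threshold for any plasticity (mV).
#' @param theta_plus Depolarisation threshold for potentiation (mV); only
#'   back-propagating spikes and NMDA plateaus exceed it.
#' @param tau_x Presynaptic spike-trace time constant (ms).
#' @param tau_minus,tau_plus Voltage low-pass time constants (ms).
#' @param tau_1 Extra filter time constant of the `"detailed_u1"` variant (ms).
#' @param x_reset Spike-trace increment per presynaptic spike.
#' @param eps Voltage delay of the `"reduced_delay"` variant (ms); rounded to
#'   whole steps at run time.
#' @param w_min,w_max Hard weight bounds.
#' @param dltp_scale Multiplier on `a_ltp` while an NMDA plateau is detected.
#' @param dltp_lookback Plateau detection lookback (ms); must exceed the
#'   somatic spike width so that spikes alone can never trigger it.
#' @param variant Filter/delay variant; defaults to match the preset.
#' @return A named list of class `"plasticity_params"`.
#' @export
#' @examples
#' plasticity_params()            # point-neuron rule
#' plasticity_params("detailed")  # morphological-model rule
plasticity_params <- function(preset = c("reduced", "detailed"),
                              a_ltd = NULL, a_ltp = NULL,
                              theta_minus = NULL, theta_plus = -15,
                              tau_x = NULL, tau_minus = NULL, tau_plus = NULL,
                              tau_1 = 5, x_reset = NULL, eps = 1,
                              w_min = 0.01, w_max = 1,
                              dltp_scale = 0.15, dltp_lookback = 1.3,
                              variant = NULL) {
  preset <- match.arg(preset)
  red <- preset == "reduced"
  if (is.null(a_ltd)) a_ltd <- if (red) 5e-4 else 4e-4
  if (is.null(a_ltp)) a_ltp <- if (red) 15e-4 else 14e-4
  if (is.null(theta_minus)) theta_minus <- -69
  if (is.null(tau_x)) tau_x <- if (red) 15 else 20
  if (is.null(tau_minus)) tau_minus <- if (red) 35 else 15
  if (is.null(tau_plus)) tau_plus <- if (red) 35 else 45
  if (is.null(x_reset)) x_reset <- if (red) 1 else 5
  if (is.null(variant)) variant <- if (red) "reduced_delay" else "detailed_u1"
  variant <- match.arg(variant, c("reduced_delay", "detailed_u1"))
  if (theta_plus <= theta_minus) {
    stop("plasticity_params: `theta_plus` must exceed `theta_minus`",
      call. = FALSE
    )
  }
  if (a_ltd < 0 || a_ltp < 0) {
    stop("plasticity_params: amplitudes must be non-negative", call. = FALSE)
  }
  if (w_min >= w_max) {
    stop("plasticity_params: `w_min` must lie below `w_max`", call. = FALSE)
  }
  structure(
    list(
      preset = preset, a_ltd = a_ltd, a_ltp = a_ltp,
      theta_minus = theta_minus, theta_plus = theta_plus,
      tau_x = tau_x, tau_minus = tau_minus, tau_plus = tau_plus,
      tau_1 = tau_1, x_reset = x_reset, eps = eps,
      w_min = w_min, w_max = w_max,
      dltp_scale = dltp_scale, dltp_lookback = dltp_lookback,
      variant = variant
    ),
    class = "plasticity_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> dt =", x$dt, "ms, C =", x$c_m, "pF, g_L =", x$g_l,
      "nS, E_L =", x$e_l, "mV,", x$n_dendrites, "dendrites\n")
  invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params> preset =", x$preset, "(", x$variant, ")",
      "A_LTD =", x$a_ltd, "A_LTP =", x$a_ltp,
      "bounds = [", x$w_min, ",", x$w_max, "]\n")
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params> preset =", x$preset,
      "g_AMPA =", x$g_ampa_max, "nS, g_NMDA =", x$g_nmda,
      "nS, distal gain =", x$distal_gain, "\n")
  invisible(x)
}

#' Read or write parameter presets
#'
#' Parameter sets serialise to YAML (or JSON) keyed by their field names, so
#' presets can be shipped alongside protocol configurations.
#'
#' @param params A `neuron_params`, `synapse_params`, `plasticity_params` or
#'   `noise_params` object.
#' @param path File to write to / read from (`.yaml`, `.yml` or `.json`).
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   the reconstructed parameter object.
#' @export
write_params <- function(params, path) {
  cls <- class(params)[1]
  body <- c(list(.class = cls), unclass(params))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(body, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  body <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cls <- body$.class
  body$.class <- NULL
  ctor <- switch(cls,
    neuron_params = neuron_params,
    synapse_params = synapse_params,
    plasticity_params = plasticity_params,
    noise_params = noise_params,
    stop("read_params: unknown parameter class ", cls, call. = FALSE)
  )
  if (cls %in% c("synapse_params", "plasticity_params")) {
    body$preset <- NULL
    # presets are re-derivable; stored fields take precedence anyway
  }
  do.call(ctor, body)
}
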