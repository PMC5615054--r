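#' Voltage dependence of the NMDA-receptor magnesium block
#'
#' Fraction of the NMDA conductance available at membrane voltage `v`:
#' `B(v) = 1 / (1 + exp(-0.062 v) / 3.57)`. Strictly increasing in `v` and
#' bounded in (0, 1); its supralinearity near -40 to -20 mV is what lets
#' clustered synaptic input regenerate into an NMDA spike.
#'
#' @param v Membrane voltage (mV); vectorised.
#' @return Unblocked fraction in (0, 1).
#' @export
#' @examples
#' mg_block(0)    # ~0.781
#' mg_block(-65)  # ~0.060
mg_block <- function(v) {
  1 / (1 + exp(-0.062 * v) / 3.57)
}

#' Somatic exponential (spike-initiation) current
#'
#' `I_exp = g_L * Delta_T * exp((u - V_T) / Delta_T)`, the phenomenological
#' sodium-activation current of the exponential integrate-and-fire soma.
#' The exponent is capped so that the current stays finite in the one or two
#' steps between threshold crossing and the spike voltage hold.
#'
#' @param u Somatic voltage (mV); vectorised.
#' @param v_t Current adaptive threshold (mV).
#' @param params A [neuron_params()] object.
#' @return Current in pA.
#' @export
#' @examples
#' p <- neuron_params()
#' exp_current(p$v_t_rest, p$v_t_rest, p) # g_L * Delta_T = 80 pA
exp_current <- function(u, v_t, params) {
  stopifnot(all(is.finite(u)), all(is.finite(v_t)))
  params$g_l * params$delta_t * exp(pmin((u - v_t) / params$delta_t, 30))
}

#' One relaxation step of the adaptive spike threshold
#'
#' The threshold jumps to `v_t_max` at every somatic spike and relaxes back
#' to `v_t_rest` with time constant `tau_v_t`. The update uses the exact
#' exponential decay over `dt`.
#'
#' @param v_t Current threshold value(s) (mV).
#' @param dt Step (ms).
#' @param params A [neuron_params()] object.
#' @return Updated threshold (mV).
#' @export
update_threshold <- function(v_t, dt, params) {
  params$v_t_rest + (v_t - params$v_t_rest) * exp(-dt / params$tau_v_t)
}

#' Rectified axial currents between soma, proximal and distal compartments
#'
#' Each coupling direction has its own conductance, and each term is engaged
#' only for one sign of the voltage difference. The soma receives current
#' only from proximal compartments that are more depolarised than it
#' (through 50 nS per dendrite); it never loses charge axially, because
#' forward spike propagation is modelled by the voltage holds of the
#' back-propagating action potential instead.
#'
#' Two sign conventions are available. The default, `"diffusive"`, moves
#' charge down the voltage gradient with direction-dependent conductances:
#' a proximal compartment gains `2500 nS * (u_soma - u_prox)` when the soma
#' is higher and loses `1250 nS * (u_prox - u_soma)` otherwise, and the
#' proximal-distal pair exchanges charge conservatively through 1500 nS in
#' the forward (prox to dist) and 225 nS in the backward direction.
#' `"as_printed"` evaluates the published equations literally; under that
#' convention the soma-proximal coupling is anti-diffusive (a single somatic
#' spike ignites a runaway positive-feedback loop) and an elevated distal
#' compartment is drained through 1500 nS (which makes NMDA plateaus
#' unreachable), so it is provided for reference and comparison only.
#'
#' @param u_soma Somatic voltage (mV, scalar per neuron).
#' @param u_prox,u_dist Proximal and distal voltages, one per dendrite (mV).
#' @param params A [neuron_params()] object.
#' @param convention `"diffusive"` (default) or `"as_printed"`.
#' @return A list with `soma` (scalar, pA), `prox` and `dist` (per-dendrite
#'   vectors, pA).
#' @export
#' @examples
#' p <- neuron_params(n_dendrites = 1)
#' axial_currents(-69, -59, -59, p)$soma # +500 pA into the soma
axial_currents <- function(u_soma, u_prox, u_dist, params,
                           convention = c("diffusive", "as_printed")) {
  convention <- match.arg(convention)
  if (length(u_prox) != length(u_dist)) {
    stop("axial_currents: `u_prox` and `u_dist` must have equal length",
      call. = FALSE
    )
  }
  if (length(u_soma) != 1) {
    stop("axial_currents: `u_soma` must be a single voltage", call. = FALSE)
  }
  dsp <- u_soma - u_prox
  dpd <- u_prox - u_dist
  neg <- function(x) pmin(x, 0)
  pos <- function(x) pmax(x, 0)
  i_soma <- -sum(params$g_soma_from_prox * neg(dsp))
  if (convention == "diffusive") {
    i_prox <- params$g_prox_from_soma_backward * neg(dsp) +
      params$g_prox_from_soma_forward * pos(dsp) -
      params$g_prox_dist_backward * neg(dpd) -
      params$g_prox_dist_forward * pos(dpd)
    i_dist <- params$g_dist_prox_forward * pos(dpd) +
      params$g_dist_prox_backward * neg(dpd)
  } else {
    i_prox <- -params$g_prox_from_soma_backward * neg(dsp) -
      params$g_prox_from_soma_forward * pos(dsp) -
      params$g_prox_dist_backward * neg(dpd) -
      params$g_prox_dist_forward * pos(dpd)
    i_dist <- -params$g_dist_prox_forward * pos(-dpd) -
      params$g_dist_prox_backward * neg(-dpd)
  }
  list(soma = i_soma, prox = i_prox, dist = i_dist)
}

#' One step of the coloured somatic noise current
#'
#' Advances the Ornstein-Uhlenbeck noise state by `dt` using the exact
#' transition (exponential decay plus a Gaussian increment with matched
#' stationary variance), so the stationary mean and standard deviation of
#' the emitted current equal `params$mean` and `params$sd` at any step size,
#' and the autocorrelation decays with `params$tau`.
#'
#' For the `"main_text"` form the state is the dimensionless filtered noise
#' `s(t)` and the current is `sqrt(2 tau) * s * sd + mean`; for the `"fig5"`
#' form the state is the current itself. [ou_noise_state()] gives the
#' matching initial state.
#'
#' @param s Noise state vector (one element per neuron).
#' @param params A [noise_params()] object.
#' @param dt Step (ms).
#' @return A list with the updated `s` and the emitted `current` (pA).
#' @export
ou_noise_step <- function(s, params, dt) {
  rho <- exp(-dt / params$tau)
  q <- sqrt(1 - rho^2)
  if (params$form == "main_text") {
    sd_s <- 1 / sqrt(2 * params$tau)
    s2 <- rho * s + q * sd_s * stats::rnorm(length(s))
    list(s = s2, current = sqrt(2 * params$tau) * s2 * params$sd + params$mean)
  } else {
    s2 <- params$mean + rho * (s - params$mean) +
      q * params$sd * stats::rnorm(length(s))
    list(s = s2, current = s2)
  }
}

#' @rdname ou_noise_step
#' @param n Number of independent noise states.
#' @export
ou_noise_state <- function(params, n = 1) {
  if (params$form == "main_text") rep(0, n) else rep(params$mean, n)
}

#' Simulate a long coloured-noise current trace
#'
#' Convenience wrapper generating `n_steps` of the noise current with a
#' recursive filter (equivalent to iterating [ou_noise_step()], but fast
#' enough for moment checks over millions of steps).
#'
#' @param n_steps Number of steps.
#' @inheritParams ou_noise_step
#' @return Numeric vector of currents (pA), length `n_steps`.
#' @export
#' @examples
#' np <- noise_params(mean = 35, sd = 3.5, tau = 20, form = "fig5")
#' x <- ou_noise_series(1e4, np, dt = 0.25)
#' c(mean(x), sd(x))
ou_noise_series <- function(n_steps, params, dt) {
  rho <- exp(-dt / params$tau)
  q <- sqrt(1 - rho^2)
  if (params$sd == 0) {
    return(rep(params$mean, n_steps))
  }
  innov <- stats::rnorm(n_steps, sd = q * params$sd)
  dev <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  dev + params$mean
}
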