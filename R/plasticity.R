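#' NMDA-plateau gate for dendritic LTP scaling
#'
#' The potentiation amplitude is reduced (multiplied by `dltp_scale`) while
#' the local voltage has been above the potentiation threshold continuously
#' for longer than a somatic spike lasts: the gate is open when both the
#' current voltage and the voltage `dltp_lookback` ms earlier exceed
#' `theta_plus`. Since a back-propagating spike holds the dendrite above
#' that threshold for only one spike width (shorter than the lookback),
#' only an NMDA plateau can open the gate.
#'
#' @param u_history Numeric vector of the compartment voltage on the `dt`
#'   grid, most recent value last.
#' @param params A [plasticity_params()] object.
#' @param dt Step (ms).
#' @return `TRUE` if the gate is open; `FALSE` otherwise (including when the
#'   history is shorter than the lookback).
#' @export
#' @examples
#' p <- plasticity_params()
#' nmda_ltp_gate(rep(-10, 30), p, dt = 0.25) # sustained plateau: TRUE
#' nmda_ltp_gate(rep(-69, 30), p, dt = 0.25) # rest: FALSE
nmda_ltp_gate <- function(u_history, params, dt = 0.25) {
  look <- max(1L, as.integer(round(params$dltp_lookback / dt)))
  m <- length(u_history)
  if (m <= look) {
    return(FALSE)
  }
  u_history[m] > params$theta_plus &&
    u_history[m - look] > params$theta_plus
}

#' Run the plasticity rule over a voltage trajectory
#'
#' Applies the full local voltage-dependent rule to one synapse given the
#' local compartment voltage on the integration grid and the presynaptic
#' spike times, using the same per-step semantics as the simulation engine:
#' exact-decay low-pass filters fed with the voltage delayed by `eps`
#' (`"reduced_delay"` variant) or through the extra `tau_1` filter
#' (`"detailed_u1"`), a per-spike depression decrement
#' `-a_ltd * (u_minus - theta_minus)+`, a continuously integrated
#' potentiation term `a_ltp * xbar * (u - theta_plus)+ * (u_plus -
#' theta_minus)+ * dt` (with the presynaptic trace incremented in the same
#' step as its spike), the NMDA-plateau amplitude scaling, and hard clipping
#' to the weight bounds after every update.
#'
#' @param u_mv Numeric vector: local voltage at each step (mV).
#' @param pre_spike_times Presynaptic spike times (ms); snapped to the grid.
#' @param params A [plasticity_params()] object.
#' @param dt Step (ms).
#' @param w0 Initial weight.
#' @param u_init Voltage assumed before the series starts (fills the delay
#'   and lookback buffers).
#' @return A tibble with one row per step: `time_ms`, `u_mv`, `xbar`,
#'   `u_minus`, `u_plus`, `gate`, `w`.
#' @export
#' @examples
#' p <- plasticity_params()
#' u <- rep(-69, 400)
#' u[100:140] <- -10 # a 10 ms plateau
#' traj <- plasticity_trajectory(u, pre_spike_times = 20, p, w0 = 0.5)
#' traj[nrow(traj), ]
plasticity_trajectory <- function(u_mv, pre_spike_times, params,
                                  dt = 0.25, w0 = 0.5, u_init = -69) {
  n <- length(u_mv)
  reduced <- params$variant == "reduced_delay"
  eps_steps <- max(1L, as.integer(round(params$eps / dt)))
  look <- max(1L, as.integer(round(params$dltp_lookback / dt)))
  dec_x <- exp(-dt / params$tau_x)
  dec_m <- exp(-dt / params$tau_minus)
  dec_p <- exp(-dt / params$tau_plus)
  dec_1 <- exp(-dt / params$tau_1)
  spike_count <- tabulate(
    pmin(pmax(floor(pre_spike_times / dt + 1e-9) + 1L, 1L), n),
    nbins = n
  )
  xbar <- 0
  um <- u_init
  upf <- u_init
  u1 <- u_init
  w <- w0
  out <- matrix(NA_real_, n, 6)
  for (k in seq_len(n)) {
    u_now <- u_mv[k]
    if (reduced) {
      u_in <- if (k > eps_steps) u_mv[k - eps_steps] else u_init
    } else {
      u1 <- u_now + (u1 - u_now) * dec_1
      u_in <- u1
    }
    if (spike_count[k] > 0) {
      # depression reads the filtered voltage just before the impulse,
      # which also marks the spike-trace increment (impulse at step start)
      w <- w - params$a_ltd * spike_count[k] *
        max(um - params$theta_minus, 0)
      w <- max(w, params$w_min)
      xbar <- xbar + params$x_reset * spike_count[k]
    }
    gate <- FALSE
    if (u_now > params$theta_plus) {
      u_then <- if (k > look) u_mv[k - look] else u_init
      gate <- reduced && u_then > params$theta_plus
      amp <- if (gate) params$dltp_scale * params$a_ltp else params$a_ltp
      upf_mid <- u_in + (upf - u_in) * exp(-dt / (2 * params$tau_plus))
      w <- w + amp * dt * xbar * exp(-dt / (2 * params$tau_x)) *
        (u_now - params$theta_plus) *
        max(upf_mid - params$theta_minus, 0)
      w <- min(w, params$w_max)
    }
    um <- u_in + (um - u_in) * dec_m
    upf <- u_in + (upf - u_in) * dec_p
    xbar <- xbar * dec_x
    out[k, ] <- c(k * dt, u_now, xbar, um, upf, w)
  }
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- c("time_ms", "u_mv", "xbar", "u_minus", "u_plus", "w")
  res$gate <- res$u_mv > params$theta_plus &
    c(rep(u_init, min(look, n)), u_mv[seq_len(max(n - look, 0))]) >
      params$theta_plus & reduced
  res[, c(
    "time_ms", "u_mv", "xbar", "u_minus", "u_plus", "gate", "w"
  )]
}
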