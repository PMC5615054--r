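# Independent reference integrators, deliberately written as straight-line
# scalar code with plain forward Euler at a refined step. They share nothing
# with the package's exponential-Euler engine beyond the model definition.

# Reference single-neuron integrator: soma + D dendrites (prox/dist pairs),
# diffusive axial convention, optional constant currents and synaptic events
# (no noise, no spikes expected -- asserts the soma stays subthreshold).
# Returns voltages sampled at multiples of `sample_every_ms`.
ref_neuron_trace <- function(duration_ms,
                             dt = 0.25 / 16,
                             n_dend = 1,
                             i_soma = 0, i_prox = 0, i_dist = 0,
                             syn_events = NULL, # cols: time_ms, comp, dend, w
                             np = neuron_params(n_dendrites = n_dend),
                             sp = synapse_params(),
                             sample_every_ms = 0.25) {
  n <- round(duration_ms / dt)
  keep <- round(sample_every_ms / dt)
  us <- np$e_l
  upv <- rep(np$e_l, n_dend)
  udv <- rep(np$e_l, n_dend)
  v_t <- np$v_t_rest
  ga_p <- gn_p <- rep(0, n_dend)
  ga_d <- gn_d <- rep(0, n_dend)
  out <- matrix(NA_real_, floor(n / keep), 1 + 2 * n_dend)
  r <- 0L
  for (k in seq_len(n)) {
    t <- k * dt
    if (!is.null(syn_events)) {
      hit <- abs(syn_events$time_ms - t) < dt / 2
      if (any(hit)) {
        for (j in which(hit)) {
          d <- syn_events$dend[j]
          w <- syn_events$w[j]
          if (syn_events$comp[j] == "prox") {
            ga_p[d] <- ga_p[d] + w * sp$g_ampa_max
            gn_p[d] <- gn_p[d] + w * sp$g_nmda
          } else {
            ga_d[d] <- ga_d[d] + w * sp$g_ampa_max
            gn_d[d] <- gn_d[d] + w * sp$g_nmda
          }
        }
      }
    }
    i_ax_s <- 0
    new_up <- upv
    new_ud <- udv
    for (d in seq_len(n_dend)) {
      dsp <- us - upv[d]
      dpd <- upv[d] - udv[d]
      i_ax_s <- i_ax_s - np$g_soma_from_prox * min(dsp, 0)
      i_p <- np$g_prox_from_soma_backward * min(dsp, 0) +
        np$g_prox_from_soma_forward * max(dsp, 0) -
        np$g_prox_dist_backward * min(dpd, 0) -
        np$g_prox_dist_forward * max(dpd, 0)
      i_d <- np$g_dist_prox_forward * max(dpd, 0) +
        np$g_dist_prox_backward * min(dpd, 0)
      i_syn_p <- -(ga_p[d] * upv[d] + gn_p[d] * mg_block(upv[d]) * upv[d])
      i_syn_d <- -sp$distal_gain *
        (ga_d[d] * udv[d] + gn_d[d] * mg_block(udv[d]) * udv[d])
      new_up[d] <- upv[d] + dt / np$c_m *
        (-np$g_l * (upv[d] - np$e_l) + i_p + i_syn_p + i_prox)
      new_ud[d] <- udv[d] + dt / np$c_m *
        (-np$g_l * (udv[d] - np$e_l) + i_d + i_syn_d + i_dist)
    }
    i_exp <- np$g_l * np$delta_t * exp((us - v_t) / np$delta_t)
    us <- us + dt / np$c_m *
      (-np$g_l * (us - np$e_l) + i_exp + i_ax_s + i_soma)
    stopifnot(us < np$theta_spike) # reference covers subthreshold runs only
    upv <- new_up
    udv <- new_ud
    v_t <- v_t + dt / np$tau_v_t * (np$v_t_rest - v_t)
    ga_p <- ga_p - dt * ga_p / sp$tau_ampa
    gn_p <- gn_p - dt * gn_p / sp$tau_nmda
    ga_d <- ga_d - dt * ga_d / sp$tau_ampa
    gn_d <- gn_d - dt * gn_d / sp$tau_nmda
    if (k %% keep == 0) {
      r <- r + 1L
      out[r, ] <- c(us, upv, udv)
    }
  }
  colnames(out) <- c(
    "soma", paste0("prox", seq_len(n_dend)), paste0("dist", seq_len(n_dend))
  )
  out[seq_len(r), , drop = FALSE]
}

# Reference plasticity integrator: scalar loop at dt/refine over a voltage
# series given on the coarse grid (piecewise constant within a coarse step),
# plain Euler filters. Spikes are applied at the first fine substep of their
# coarse step; the realised delay/lookback (whole coarse steps) are matched.
ref_plasticity <- function(u_coarse, pre_spike_times, pp,
                           dt = 0.25, refine = 16, w0 = 0.5,
                           u_init = -69) {
  n <- length(u_coarse)
  dtf <- dt / refine
  eps_f <- max(1L, round(pp$eps / dt)) * refine
  look_f <- max(1L, round(pp$dltp_lookback / dt)) * refine
  spike_coarse <- tabulate(
    pmin(pmax(floor(pre_spike_times / dt + 1e-9) + 1L, 1L), n),
    nbins = n
  )
  xbar <- 0
  um <- u_init
  upf <- u_init
  u1 <- u_init
  w <- w0
  u_at <- function(jf) { # fine index -> voltage (piecewise constant)
    if (jf < 1) {
      return(u_init)
    }
    u_coarse[ceiling(jf / refine)]
  }
  reduced <- pp$variant == "reduced_delay"
  for (k in seq_len(n)) {
    u_now <- u_coarse[k]
    for (j in seq_len(refine)) {
      jf <- (k - 1L) * refine + j
      if (reduced) {
        u_in <- u_at(jf - eps_f)
      } else {
        u1 <- u1 + dtf / pp$tau_1 * (u_now - u1)
        u_in <- u1
      }
      um <- um + dtf / pp$tau_minus * (u_in - um)
      upf <- upf + dtf / pp$tau_plus * (u_in - upf)
      xbar <- xbar - dtf / pp$tau_x * xbar
      if (j == 1L && spike_coarse[k] > 0) {
        xbar <- xbar + pp$x_reset * spike_coarse[k]
        w <- w - pp$a_ltd * spike_coarse[k] * max(um - pp$theta_minus, 0)
        w <- max(w, pp$w_min)
      }
      if (u_now > pp$theta_plus) {
        gate <- reduced && u_at(jf - look_f) > pp$theta_plus
        amp <- if (gate) pp$dltp_scale * pp$a_ltp else pp$a_ltp
        w <- w + amp * dtf * xbar * (u_now - pp$theta_plus) *
          max(upf - pp$theta_minus, 0)
        w <- min(w, pp$w_max)
      }
    }
  }
  w
}

# A random 1-s voltage episode with rest, depolarised stretches, bAP-like
# 1 ms excursions and plateau-like stretches, on the coarse grid.
random_voltage_episode <- function(n_steps = 4000, dt = 0.25) {
  u <- rep(-69, n_steps)
  n_dep <- sample(3:6, 1)
  for (i in seq_len(n_dep)) { # slow depolarised stretches
    a <- sample.int(n_steps - 400, 1)
    u[a:(a + sample(100:400, 1))] <- -69 + runif(1, 2, 25)
  }
  for (i in seq_len(sample(5:12, 1))) { # bAP-like excursions
    a <- sample.int(n_steps - 8, 1)
    u[a:(a + 3)] <- 10
  }
  if (runif(1) < 0.7) { # plateau
    a <- sample.int(n_steps - 200, 1)
    u[a:(a + sample(40:200, 1))] <- runif(1, -12, -2)
  }
  pmin(u, 30)
}
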