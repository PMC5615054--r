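#' Run a circuit simulation
#'
#' Advances all neurons of a circuit synchronously on the `dt` grid. Each
#' step decays and jumps synaptic conductances, integrates every compartment
#' with an exponential-Euler update (all conductance-like terms, including
#' the rectified axial couplings frozen at their current branch, are folded
#' into the relaxation rate, which keeps the stiff soma-dendrite coupling
#' stable at the default 250 microsecond step), applies the spike and
#' back-propagation voltage holds, updates the plasticity traces and
#' weights, and feeds the somatic inhibition filter. Clamped compartments
#' skip integration: their voltage equals the hold value exactly, and the
#' plasticity rule sees the held voltage.
#'
#' A somatic spike is emitted when the integrated somatic voltage crosses
#' `theta_spike` outside a hold (or when a forced spike is scheduled). The
#' soma is then held at `v_spike_soma` for one spike width and reset to
#' `v_reset`; all proximal/distal compartments of the neuron are held at
#' their back-propagation values for one spike width, starting at the first
#' step boundary at or after `bap_delay` (the realised delay is reported).
#'
#' All randomness (noise, nothing else) draws from the single stream seeded
#' by `seed`; two runs with equal seeds and inputs are identical.
#'
#' @param circuit A [circuit()] or [build_network()] object.
#' @param duration_ms Simulated time (ms).
#' @param input_spikes Optional tibble of external drive with columns
#'   `time_ms` and `input_id`; each event makes every synapse whose
#'   `pre_kind == "input"` and `pre == input_id` fire at that time.
#' @param forced_spikes Optional tibble with columns `time_ms` and `neuron`:
#'   somatic spikes triggered directly (the observable equivalent of a brief
#'   suprathreshold current pulse), suppressed if the soma is already held.
#' @param i_ext Optional constant external currents: a list with any of
#'   `soma` (per neuron), `prox`, `dist` (per neuron x dendrite), in pA.
#' @param seed Integer seed.
#' @param record_weights_every Cadence of weight snapshots (ms); the initial
#'   weights are always recorded.
#' @param record_trace Optional tibble of compartments to record at full
#'   resolution, columns `neuron`, `compartment` (`"soma"|"prox"|"dist"`)
#'   and `dend` (ignored for the soma).
#' @param record_gate Count, per compartment, the steps on which the
#'   NMDA-plateau gate was open.
#' @param plasticity_on Set `FALSE` to freeze all weights.
#' @return An object of class `"dendplast_sim"`; see [tidy.dendplast_sim()].
#' @export
#' @examples
#' cc <- circuit(
#'   n_neurons = 1,
#'   synapses = tibble::tibble(
#'     pre_kind = "input", pre = 1, post = 1, dend = 1,
#'     loc = "prox", w = 0.5, plastic = TRUE
#'   ),
#'   neuron = neuron_params(n_dendrites = 1)
#' )
#' sim <- run_sim(cc, 50,
#'   input_spikes = tibble::tibble(time_ms = c(5, 10), input_id = 1)
#' )
#' glance(sim)
run_sim <- function(circuit, duration_ms,
                    input_spikes = NULL,
                    forced_spikes = NULL,
                    i_ext = NULL,
                    seed = 1,
                    record_weights_every = 1000,
                    record_trace = NULL,
                    record_gate = FALSE,
                    plasticity_on = TRUE) {
  stopifnot(inherits(circuit, "dendplast_circuit"))
  np <- circuit$neuron
  sp <- circuit$synapse
  pp <- circuit$plasticity
  nzp <- circuit$noise
  dt <- np$dt
  n <- circuit$n_neurons
  nd <- np$n_dendrites
  ncomp <- n * nd # per layer (prox / dist)
  n_steps <- as.integer(round(duration_ms / dt))
  syn <- circuit$synapses
  nsyn <- nrow(syn)

  set.seed(as.integer(seed))

  # --- synapse bookkeeping -------------------------------------------------
  comp_of <- (syn$dend - 1L) * n + syn$post # within-layer compartment index
  comp_lin <- ifelse(syn$loc == "dist", ncomp + comp_of, comp_of)
  gain_syn <- ifelse(
    syn$loc == "dist" &
      (circuit$distal_gain_recurrent | syn$pre_kind != "neuron"),
    sp$distal_gain, 1
  )
  agg <- Matrix::sparseMatrix(
    i = comp_lin, j = seq_len(nsyn), x = gain_syn,
    dims = c(2L * ncomp, nsyn)
  )
  w <- syn$w
  plastic <- which(syn$plastic)
  n_plastic <- length(plastic)
  plastic_pos <- integer(nsyn) # syn id -> position among plastic syns
  plastic_pos[plastic] <- seq_len(n_plastic)

  # recurrent fan-out: synapse ids by presynaptic neuron
  rec_idx <- which(syn$pre_kind == "neuron")
  fanout <- vector("list", n)
  if (length(rec_idx)) {
    fo <- split(rec_idx, syn$pre[rec_idx])
    fanout[as.integer(names(fo))] <- fo
  }
  # inhibition adjacency: neuron-level presynaptic neighbours
  inh <- circuit$inhibition
  if (!is.null(inh) && length(rec_idx)) {
    adj <- Matrix::sparseMatrix(
      i = syn$post[rec_idx], j = syn$pre[rec_idx], x = 1,
      dims = c(n, n), use.last.ij = TRUE
    )
    adj@x[] <- 1
  } else {
    inh <- NULL
  }

  # --- external events (aggregated per step and synapse) -------------------
  ev_starts <- NULL
  if (!is.null(input_spikes) && nrow(input_spikes)) {
    inp_syn <- which(syn$pre_kind == "input")
    by_src <- split(inp_syn, syn$pre[inp_syn])
    hits <- by_src[as.character(input_spikes$input_id)]
    lens <- lengths(hits)
    if (any(lens == 0)) {
      stop("run_sim: input_spikes reference unknown input_id", call. = FALSE)
    }
    ev_syn <- unlist(hits, use.names = FALSE)
    ev_step <- rep(
      pmin(pmax(floor(input_spikes$time_ms / dt + 1e-9) + 1L, 1L), n_steps),
      lens
    )
    key <- (ev_step - 1) * (nsyn + 1) + ev_syn
    tab <- table(key)
    key_u <- as.numeric(names(tab))
    ev_step <- as.integer(key_u %/% (nsyn + 1)) + 1L
    ev_syn <- as.integer(key_u %% (nsyn + 1))
    ev_cnt <- as.integer(tab)
    o <- order(ev_step)
    ev_step <- ev_step[o]; ev_syn <- ev_syn[o]; ev_cnt <- ev_cnt[o]
    ev_starts <- findInterval(0:n_steps, ev_step)
  }
  fs_starts <- NULL
  if (!is.null(forced_spikes) && nrow(forced_spikes)) {
    fs_step <- pmin(
      pmax(floor(forced_spikes$time_ms / dt + 1e-9) + 1L, 1L), n_steps
    )
    o <- order(fs_step)
    fs_step <- fs_step[o]
    fs_neuron <- as.integer(forced_spikes$neuron)[o]
    fs_starts <- findInterval(0:n_steps, fs_step)
  }

  # --- state ---------------------------------------------------------------
  us <- rep(np$e_l, n)
  up <- matrix(np$e_l, n, nd)
  ud <- matrix(np$e_l, n, nd)
  v_t <- rep(np$v_t_rest, n)
  g_a <- numeric(nsyn)
  g_n <- numeric(nsyn)
  s_noise <- ou_noise_state(nzp, n)
  noise_off <- nzp$sd == 0
  soma_hold <- integer(n)
  dend_delay <- integer(n)
  dend_hold <- integer(n)
  up_saved <- matrix(np$e_l, n, nd) # dendritic state under the bAP overlay
  ud_saved <- matrix(np$e_l, n, nd)
  e_in <- numeric(n)
  g_in <- numeric(n)

  xbar <- numeric(n_plastic)
  comp_p <- comp_lin[plastic]
  um_f <- rep(np$e_l, 2L * ncomp) # u-bar minus
  upf <- rep(np$e_l, 2L * ncomp) # u-bar plus
  u1_f <- rep(np$e_l, 2L * ncomp) # extra filter, detailed variant

  reduced_var <- pp$variant == "reduced_delay"
  eps_steps <- max(1L, as.integer(round(pp$eps / dt)))
  look_steps <- max(1L, as.integer(round(pp$dltp_lookback / dt)))
  buf_len <- max(eps_steps, look_steps) + 1L
  ubuf <- matrix(np$e_l, 2L * ncomp, buf_len)

  spike_steps <- as.integer(round(np$spike_width / dt))
  delay_steps <- as.integer(ceiling(np$bap_delay / dt))

  dec_a <- exp(-dt / sp$tau_ampa)
  dec_n <- exp(-dt / sp$tau_nmda)
  dec_x <- exp(-dt / pp$tau_x)
  dec_vt <- exp(-dt / np$tau_v_t)
  dec_m <- exp(-dt / pp$tau_minus)
  dec_pl <- exp(-dt / pp$tau_plus)
  dec_pl_half <- exp(-dt / (2 * pp$tau_plus))
  dec_x_half <- exp(-dt / (2 * pp$tau_x))
  dec_1 <- exp(-dt / pp$tau_1)

  nrn_row <- seq_len(n) # rows of the N x D matrices are neurons
  ie_s <- ie_p <- ie_d <- 0
  if (!is.null(i_ext)) {
    if (!is.null(i_ext$soma)) ie_s <- i_ext$soma
    if (!is.null(i_ext$prox)) ie_p <- i_ext$prox
    if (!is.null(i_ext$dist)) ie_d <- i_ext$dist
  }

  # --- recorders -----------------------------------------------------------
  spike_cap <- 1024L
  spike_t <- numeric(spike_cap)
  spike_n <- integer(spike_cap)
  n_spikes <- 0L
  snap_every <- max(1L, as.integer(round(record_weights_every / dt)))
  snap_steps <- seq(0L, n_steps, by = snap_every)
  w_snap <- matrix(NA_real_, length(snap_steps), n_plastic)
  if (n_plastic) w_snap[1, ] <- w[plastic]
  snap_ptr <- 1L

  tr_idx <- NULL
  if (!is.null(record_trace) && nrow(record_trace)) {
    rt <- record_trace
    tr_idx <- integer(nrow(rt))
    for (r in seq_len(nrow(rt))) {
      tr_idx[r] <- switch(rt$compartment[r],
        soma = -rt$neuron[r],
        prox = (rt$dend[r] - 1L) * n + rt$neuron[r],
        dist = ncomp + (rt$dend[r] - 1L) * n + rt$neuron[r],
        stop("record_trace: compartment must be soma/prox/dist",
          call. = FALSE
        )
      )
    }
    trace <- matrix(NA_real_, n_steps, length(tr_idx))
    tr_soma <- tr_idx < 0
    tr_soma_id <- -tr_idx[tr_soma]
    tr_dend_id <- tr_idx[!tr_soma]
  }
  gate_count <- if (record_gate) integer(2L * ncomp) else NULL

  theta_mp <- pp$theta_minus
  theta_pp <- pp$theta_plus

  # --- main loop -----------------------------------------------------------
  prev_spiked <- integer(0)
  for (k in seq_len(n_steps)) {
    # conductance decay + spike-triggered jumps
    g_a <- g_a * dec_a
    g_n <- g_n * dec_n
    ltd_syn <- integer(0)
    ltd_cnt <- integer(0)
    if (!is.null(ev_starts) && ev_starts[k + 1] > ev_starts[k]) {
      sl <- (ev_starts[k] + 1):ev_starts[k + 1]
      js <- ev_syn[sl]
      jc <- ev_cnt[sl]
      g_a[js] <- g_a[js] + w[js] * sp$g_ampa_max * jc
      g_n[js] <- g_n[js] +
        (if (sp$nmda_scales_with_w) w[js] else 1) * sp$g_nmda * jc
      keep <- syn$plastic[js]
      if (any(keep)) {
        ltd_syn <- js[keep]
        ltd_cnt <- jc[keep]
      }
    }
    if (length(prev_spiked)) {
      js <- unlist(fanout[prev_spiked], use.names = FALSE)
      if (length(js)) {
        g_a[js] <- g_a[js] + w[js] * sp$g_ampa_max
        g_n[js] <- g_n[js] +
          (if (sp$nmda_scales_with_w) w[js] else 1) * sp$g_nmda
        keep <- syn$plastic[js]
        if (any(keep)) {
          ltd_syn <- c(ltd_syn, js[keep])
          ltd_cnt <- c(ltd_cnt, rep(1L, sum(keep)))
        }
      }
    }

    # aggregate synaptic conductances per compartment (distal gain folded in)
    g_comp <- as.matrix(agg %*% cbind(g_a, g_n))
    ga_p <- matrix(g_comp[seq_len(ncomp), 1], n, nd)
    ga_d <- matrix(g_comp[ncomp + seq_len(ncomp), 1], n, nd)
    gn_p <- matrix(g_comp[seq_len(ncomp), 2], n, nd)
    gn_d <- matrix(g_comp[ncomp + seq_len(ncomp), 2], n, nd)

    # axial branch conductances (rectification = branch selection)
    dsp <- us - up # soma minus prox, N x D (us recycles down columns)
    soma_higher <- dsp > 0
    g_sp_p <- ifelse(
      soma_higher, np$g_prox_from_soma_forward, np$g_prox_from_soma_backward
    )
    # while the soma is held at the spike voltage, the dendrites do not see
    # it through the axial coupling: back-propagation is carried entirely by
    # the scheduled dendritic holds, keeping the realised dendritic spike
    # height at the stated hold values
    held_soma_pre <- soma_hold > 0L
    if (any(held_soma_pre)) g_sp_p[held_soma_pre, ] <- 0
    dpd <- up - ud
    prox_higher <- dpd > 0
    g_pd_p <- ifelse(
      prox_higher, np$g_prox_dist_forward, np$g_dist_prox_backward
    )
    g_pd_d <- ifelse(
      prox_higher, np$g_dist_prox_forward, np$g_dist_prox_backward
    )

    # noise and somatic point currents
    if (noise_off) {
      ns <- list(current = nzp$mean)
    } else {
      ns <- ou_noise_step(s_noise, nzp, dt)
      s_noise <- ns$s
    }
    i_exp <- np$g_l * np$delta_t * exp(pmin((us - v_t) / np$delta_t, 30))

    # soma: gains only from more-depolarised proximal compartments; the bAP
    # hold is an imposed overlay and must not source current into the soma
    gain_mask <- (!soma_higher) * np$g_soma_from_prox
    bap_active <- dend_hold > 0L | dend_delay > 0L
    if (any(bap_active)) gain_mask[bap_active, ] <- 0
    g_soma_ax <- rowSums(gain_mask)
    b_soma_ax <- rowSums(gain_mask * up)
    g_s <- np$g_l + g_soma_ax
    b_s <- np$g_l * np$e_l + b_soma_ax + i_exp + ns$current + ie_s
    if (!is.null(inh)) {
      g_inh <- inh$a_inhib * g_in
      g_s <- g_s + g_inh
      b_s <- b_s + g_inh * inh$e_gaba
    }

    # NMDA block at current local voltage
    bf_p <- mg_block(up)
    bf_d <- mg_block(ud)

    g_p <- np$g_l + g_sp_p + g_pd_p + ga_p + gn_p * bf_p
    b_p <- np$g_l * np$e_l + g_sp_p * us + g_pd_p * ud +
      ga_p * sp$e_ampa + gn_p * bf_p * sp$e_nmda + ie_p
    g_d <- np$g_l + g_pd_d + ga_d + gn_d * bf_d
    b_d <- np$g_l * np$e_l + g_pd_d * up +
      ga_d * sp$e_ampa + gn_d * bf_d * sp$e_nmda + ie_d

    # exponential-Euler relaxation towards b/G
    uinf <- b_s / g_s
    us <- uinf + (us - uinf) * exp(-g_s * dt / np$c_m)
    uinf <- b_p / g_p
    up <- uinf + (up - uinf) * exp(-g_p * dt / np$c_m)
    uinf <- b_d / g_d
    ud <- uinf + (ud - uinf) * exp(-g_d * dt / np$c_m)
    v_t <- np$v_t_rest + (v_t - np$v_t_rest) * dec_vt

    if (anyNA(us) || any(!is.finite(us))) {
      bad <- which(!is.finite(us))[1]
      stop(
        "run_sim: non-finite somatic voltage in neuron ", bad,
        " at t = ", k * dt, " ms",
        call. = FALSE
      )
    }

    # spike detection (suppressed during the somatic hold)
    spiked <- which(us >= np$theta_spike & soma_hold == 0L)
    if (!is.null(fs_starts) && fs_starts[k + 1] > fs_starts[k]) {
      fsn <- fs_neuron[(fs_starts[k] + 1):fs_starts[k + 1]]
      fsn <- fsn[soma_hold[fsn] == 0L]
      spiked <- union(spiked, fsn)
    }
    if (length(spiked)) {
      # remember the dendritic state so the compartments resume from it when
      # the bAP overlay ends (an ongoing plateau survives a somatic spike);
      # during a rapid burst, keep the baseline saved at the first spike
      fresh <- spiked[dend_delay[spiked] == 0L & dend_hold[spiked] == 0L]
      if (length(fresh)) {
        up_saved[fresh, ] <- up[fresh, ]
        ud_saved[fresh, ] <- ud[fresh, ]
      }
      soma_hold[spiked] <- spike_steps
      dend_delay[spiked] <- delay_steps
      dend_hold[spiked] <- 0L
      v_t[spiked] <- np$v_t_max
    }

    # voltage holds (clamped compartments take the hold value exactly)
    held_s <- soma_hold > 0L
    if (any(held_s)) us[held_s] <- np$v_spike_soma
    held_d <- dend_hold > 0L
    if (any(held_d)) {
      up[held_d, ] <- np$v_bap_prox
      ud[held_d, ] <- np$v_bap_dist
    }

    # plasticity (sees post-hold voltages of the local compartment)
    udv <- c(up, ud)
    slot <- (k - 1L) %% buf_len + 1L
    ubuf[, slot] <- udv
    if (plasticity_on && n_plastic) {
      if (reduced_var) {
        u_in <- if (k > eps_steps) {
          ubuf[, (k - eps_steps - 1L) %% buf_len + 1L]
        } else {
          ubuf[, 1L] * 0 + np$e_l
        }
      } else {
        u1_f <- udv + (u1_f - udv) * dec_1
        u_in <- u1_f
      }
      # depression fires on the presynaptic impulse and reads the filtered
      # voltage just before it (pre-update value)
      if (length(ltd_syn)) {
        dep <- pp$a_ltd * ltd_cnt * pmax(um_f[comp_lin[ltd_syn]] - theta_mp, 0)
        w[ltd_syn] <- pmax(w[ltd_syn] - dep, pp$w_min)
        ppx <- plastic_pos[ltd_syn]
        xbar[ppx] <- xbar[ppx] + pp$x_reset * ltd_cnt # impulse at step start
      }
      ltp_on <- max(udv) > theta_pp
      if (ltp_on) {
        # potentiation integrates over the step with mid-step trace and
        # filter values (the voltage itself is constant within a step)
        pot <- pmax(udv - theta_pp, 0)
        if (reduced_var) {
          gate <- pot > 0 & (if (k > look_steps) {
            ubuf[, (k - look_steps - 1L) %% buf_len + 1L] > theta_pp
          } else {
            FALSE
          })
          if (record_gate) gate_count <- gate_count + gate
          amp <- ifelse(gate[comp_p], pp$dltp_scale, 1) * pp$a_ltp
        } else {
          amp <- pp$a_ltp
        }
        upf_mid <- u_in + (upf - u_in) * dec_pl_half
        dwp <- amp * dt * (xbar * dec_x_half) * pot[comp_p] *
          pmax(upf_mid[comp_p] - theta_mp, 0)
        if (any(dwp > 0)) {
          w[plastic] <- pmin(w[plastic] + dwp, pp$w_max)
        }
      }
      um_f <- u_in + (um_f - u_in) * dec_m
      upf <- u_in + (upf - u_in) * dec_pl
      xbar <- xbar * dec_x
    }

    # inhibition filters driven by this step's spikes (arrive next step)
    if (!is.null(inh)) {
      cnt <- if (length(spiked)) {
        ind <- numeric(n)
        ind[spiked] <- 1
        as.numeric(adj %*% ind)
      } else {
        0
      }
      e_in <- e_in * exp(-dt / inh$tau_inhib) + cnt
      g_in <- e_in + (g_in - e_in) * exp(-dt / inh$tau_rise)
    }

    # recording
    if (length(spiked)) {
      nsp <- length(spiked)
      if (n_spikes + nsp > spike_cap) {
        spike_cap <- max(2L * spike_cap, n_spikes + nsp)
        spike_t <- c(spike_t, numeric(spike_cap - length(spike_t)))
        spike_n <- c(spike_n, integer(spike_cap - length(spike_n)))
      }
      spike_t[n_spikes + seq_len(nsp)] <- k * dt
      spike_n[n_spikes + seq_len(nsp)] <- spiked
      n_spikes <- n_spikes + nsp
    }
    if (!is.null(tr_idx)) {
      if (any(tr_soma)) trace[k, tr_soma] <- us[tr_soma_id]
      if (length(tr_dend_id)) trace[k, !tr_soma] <- udv[tr_dend_id]
    }
    if (snap_ptr < length(snap_steps) && k == snap_steps[snap_ptr + 1L]) {
      snap_ptr <- snap_ptr + 1L
      if (n_plastic) w_snap[snap_ptr, ] <- w[plastic]
    }

    # hold bookkeeping: decrement after the step's value was recorded
    if (any(held_s)) {
      soma_hold[held_s] <- soma_hold[held_s] - 1L
      rel <- held_s & soma_hold == 0L
      if (any(rel)) us[rel] <- np$v_reset
    }
    if (any(held_d)) {
      dend_hold[held_d] <- dend_hold[held_d] - 1L
      done <- held_d & dend_hold == 0L
      if (any(done)) {
        up[done, ] <- up_saved[done, ]
        ud[done, ] <- ud_saved[done, ]
      }
    }
    pending <- dend_delay > 0L
    if (any(pending)) {
      dend_delay[pending] <- dend_delay[pending] - 1L
      fire <- pending & dend_delay == 0L
      if (any(fire)) dend_hold[fire] <- spike_steps
    }
    prev_spiked <- spiked
  }

  # --- assemble result -----------------------------------------------------
  syn_out <- syn
  syn_out$w <- w
  weights <- NULL
  if (n_plastic) {
    weights <- tibble::tibble(
      time_ms = rep(snap_steps * dt, each = n_plastic),
      syn_id = rep(syn$syn_id[plastic], length(snap_steps)),
      w = as.vector(t(w_snap))
    )
  }
  trace_tbl <- NULL
  if (!is.null(tr_idx)) {
    trace_tbl <- tibble::tibble(
      time_ms = rep(seq_len(n_steps) * dt, times = length(tr_idx)),
      neuron = rep(record_trace$neuron, each = n_steps),
      compartment = rep(record_trace$compartment, each = n_steps),
      dend = rep(record_trace$dend, each = n_steps),
      u_mv = as.vector(trace)
    )
  }
  gate_tbl <- NULL
  if (record_gate) {
    gate_tbl <- tibble::tibble(
      neuron = rep(rep(nrn_row, nd), 2),
      dend = rep(rep(seq_len(nd), each = n), 2),
      compartment = rep(c("prox", "dist"), each = ncomp),
      gate_steps = as.integer(gate_count)
    )
  }
  structure(
    list(
      spikes = tibble::tibble(
        time_ms = spike_t[seq_len(n_spikes)],
        neuron = spike_n[seq_len(n_spikes)]
      ),
      weights = weights,
      synapses = syn_out,
      trace = trace_tbl,
      gate = gate_tbl,
      final_state = list(u_soma = us, u_prox = up, u_dist = ud, v_t = v_t),
      realized = list(
        dt = dt,
        bap_delay_ms = delay_steps * dt,
        eps_ms = eps_steps * dt,
        dltp_lookback_ms = look_steps * dt
      ),
      duration_ms = duration_ms,
      seed = seed
    ),
    class = "dendplast_sim"
  )
}

#' @export
print.dendplast_sim <- function(x, ...) {
  cat(
    "<dendplast_sim>", x$duration_ms, "ms,",
    nrow(x$spikes), "spikes,",
    sum(x$synapses$plastic), "plastic synapses\n"
  )
  invisible(x)
}
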