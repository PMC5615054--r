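#' Single-neuron circuit with one clustered group of driven synapses
#'
#' Convenience constructor used by the single-cell protocols: one reduced
#' neuron, with `n_syn` externally driven synapses clustered on the stated
#' compartment of one dendrite. Each synapse gets its own input source id
#' (equal to its row number).
#'
#' @param location `"prox"` or `"dist"`.
#' @param n_syn Number of synapses in the cluster.
#' @param w0 Initial weight.
#' @param dend Dendrite index.
#' @param plastic Are the synapses plastic?
#' @param neuron,synapse,plasticity,noise Parameter objects; the default
#'   neuron is trimmed to two dendrites (unused dendrites rest at the leak
#'   potential and do not affect the soma).
#' @return A `"dendplast_circuit"`.
#' @export
clustered_input_circuit <- function(location = c("prox", "dist"),
                                    n_syn = 1, w0 = 0.5, dend = 1,
                                    plastic = TRUE,
                                    neuron = neuron_params(n_dendrites = 2),
                                    synapse = synapse_params(),
                                    plasticity = plasticity_params(),
                                    noise = noise_params()) {
  location <- match.arg(location)
  circuit(
    n_neurons = 1,
    synapses = tibble::tibble(
      pre_kind = "input", pre = seq_len(n_syn), post = 1L,
      dend = dend, loc = location, w = w0, plastic = plastic
    ),
    neuron = neuron, synapse = synapse, plasticity = plasticity,
    noise = noise
  )
}

#' Spike-pairing (STDP) protocol
#'
#' Reproduces the classic pairing experiment on the reduced neuron: a
#' plastic synapse at a proximal or distal compartment is activated `n_pairs`
#' times, each presynaptic spike paired with a forced somatic spike
#' `delta_t_ms` later (`pre_post`) or earlier (`post_pre`), the pairs
#' repeating at each frequency in `frequencies`. The weight change after the
#' pairings is multiplied by `scale` (mimicking the many-repetition
#' experimental induction) and reported relative to the initial weight, so a
#' ratio below 1 is depression and above 1 potentiation.
#'
#' @param frequencies Pairing frequencies (Hz).
#' @param delta_t_ms Within-pair interval (ms).
#' @param side `"pre_post"`, `"post_pre"` or both.
#' @param location `"prox"`, `"dist"` or both.
#' @param n_pairs Number of pairings.
#' @param scale Protocol weight-change multiplier.
#' @param w0 Initial weight.
#' @param tail_ms Silent time simulated after the last pairing.
#' @param plasticity,synapse,neuron Parameter objects.
#' @return A tibble with columns `freq_hz`, `side`, `location`, `w_final`
#'   and `ratio` (`(w0 + scale * (w_final - w0)) / w0`).
#' @export
#' @examples
#' protocol_pairing(frequencies = c(1, 50), side = "pre_post")
protocol_pairing <- function(frequencies = c(1, seq(5, 50, by = 5)),
                             delta_t_ms = 10,
                             side = c("pre_post", "post_pre"),
                             location = "prox",
                             n_pairs = 6, scale = 15, w0 = 0.5,
                             tail_ms = 100,
                             plasticity = plasticity_params(),
                             synapse = synapse_params(),
                             neuron = neuron_params(n_dendrites = 2)) {
  side <- match.arg(side, several.ok = TRUE)
  location <- match.arg(location, c("prox", "dist"), several.ok = TRUE)
  grid <- expand.grid(
    freq_hz = frequencies, side = side, location = location,
    stringsAsFactors = FALSE
  )
  res <- purrr::pmap(grid, function(freq_hz, side, location) {
    period <- 1000 / freq_hz
    onsets <- (seq_len(n_pairs) - 1) * period
    if (side == "pre_post") {
      pre_t <- onsets
      post_t <- onsets + delta_t_ms
    } else {
      post_t <- onsets
      pre_t <- onsets + delta_t_ms
    }
    cc <- clustered_input_circuit(
      location = location, n_syn = 1, w0 = w0,
      neuron = neuron, synapse = synapse, plasticity = plasticity
    )
    sim <- run_sim(
      cc,
      duration_ms = max(pre_t, post_t) + tail_ms,
      input_spikes = tibble::tibble(time_ms = pre_t, input_id = 1),
      forced_spikes = tibble::tibble(time_ms = post_t, neuron = 1),
      record_weights_every = 1e6
    )
    w_final <- sim$synapses$w[1]
    tibble::tibble(
      w_final = w_final,
      ratio = (w0 + scale * (w_final - w0)) / w0
    )
  })
  dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
}

#' Poisson rate-dependent plasticity protocol
#'
#' A cluster of synapses on one proximal or distal compartment is driven by
#' independent Poisson trains at a common rate for a fixed window, and the
#' mean final weight is recorded. At distal compartments the NMDA-spike
#' pathway lets potentiation appear at much lower rates than at proximal
#' compartments, where potentiation requires somatic firing.
#'
#' @param rates Activation rates (Hz).
#' @param location `"prox"`, `"dist"` or both.
#' @param n_syn Synapses in the cluster.
#' @param w0 Initial weight.
#' @param duration_ms Drive window (ms).
#' @param tail_ms Extra simulated time for conductances/plasticity to settle.
#' @param n_reps Independent repetitions per rate.
#' @param seed Master seed.
#' @param plasticity,synapse,neuron Parameter objects.
#' @return Tibble with `rate_hz`, `location`, `rep`, `mean_w_final`.
#' @export
protocol_rate_ltp <- function(rates = c(1, seq(10, 70, by = 10)),
                              location = c("prox", "dist"),
                              n_syn = 10, w0 = 0.5,
                              duration_ms = 200, tail_ms = 200,
                              n_reps = 3, seed = 1,
                              plasticity = plasticity_params(),
                              synapse = synapse_params(),
                              neuron = neuron_params(n_dendrites = 2)) {
  location <- match.arg(location, several.ok = TRUE)
  grid <- expand.grid(
    rate_hz = rates, location = location, rep = seq_len(n_reps),
    stringsAsFactors = FALSE
  )
  res <- purrr::pmap(grid, function(rate_hz, location, rep) {
    run_seed <- seed + 7919L * rep +
      31L * round(rate_hz) + 1000L * (location == "dist")
    set.seed(run_seed)
    trains <- lapply(seq_len(n_syn), function(i) {
      poisson_train(rate_hz, duration_ms, dt = neuron$dt)
    })
    lens <- lengths(trains)
    spikes <- tibble::tibble(
      time_ms = unlist(trains, use.names = FALSE),
      input_id = rep(seq_len(n_syn), lens)
    )
    cc <- clustered_input_circuit(
      location = location, n_syn = n_syn, w0 = w0,
      neuron = neuron, synapse = synapse, plasticity = plasticity
    )
    sim <- run_sim(cc, duration_ms + tail_ms,
      input_spikes = spikes, seed = run_seed,
      record_weights_every = 1e6
    )
    tibble::tibble(mean_w_final = mean(sim$synapses$w))
  })
  dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
}

#' Lowest rate producing net potentiation
#'
#' @param rate_result Output of [protocol_rate_ltp()].
#' @param w0 The initial weight used.
#' @return Tibble with one row per location: `onset_rate_hz`, the lowest
#'   tested rate whose mean final weight (across repetitions) exceeds `w0`
#'   (`Inf` if none does).
#' @export
ltp_onset_rate <- function(rate_result, w0 = 0.5) {
  rate_result |>
    dplyr::group_by(.data$location, .data$rate_hz) |>
    dplyr::summarise(mean_w = mean(.data$mean_w_final), .groups = "drop_last") |>
    dplyr::summarise(
      onset_rate_hz = if (any(.data$mean_w > w0)) {
        min(.data$rate_hz[.data$mean_w > w0])
      } else {
        Inf
      },
      .groups = "drop"
    )
}

#' Classify a neuron pair's connectivity change
#'
#' A direction counts as strengthened when the mean of its synaptic weights
#' is strictly larger at the end of the simulation than at the start (a tie
#' is not strengthened). Both directions strengthened is `"bidirectional"`,
#' one is `"unidirectional_12"`/`"unidirectional_21"`, neither is
#' `"unconnected"`.
#'
#' @param w12_before,w12_after Weights of the 1-to-2 synapses before/after.
#' @param w21_before,w21_after Weights of the 2-to-1 synapses before/after.
#' @return A single classification string.
#' @export
#' @examples
#' classify_connectivity(0.5, 0.9, 0.5, 0.2) # unidirectional_12
classify_connectivity <- function(w12_before, w12_after,
                                  w21_before, w21_after) {
  up12 <- mean(w12_after) > mean(w12_before)
  up21 <- mean(w21_after) > mean(w21_before)
  if (up12 && up21) {
    "bidirectional"
  } else if (up12) {
    "unidirectional_12"
  } else if (up21) {
    "unidirectional_21"
  } else {
    "unconnected"
  }
}

#' Temporal-order protocol for a reciprocally connected pair
#'
#' Two reduced neurons are reciprocally connected by `n_syn` synapses each
#' way, clustered on one compartment of the stated kind. Spikes are induced
#' in neuron 1 during the first 10 ms of each cycle and in neuron 2 during
#' the following 10 ms (Poisson at `rate_hz` within each window); 250 ms of
#' silence completes the 270 ms cycle, repeated `n_cycles` times. The
#' resulting weight changes are classified with [classify_connectivity()]:
#' proximal clusters report the temporal order (unidirectional 1-to-2),
#' distal clusters let NMDA plateaus potentiate both directions.
#'
#' @param location `"prox"` or `"dist"`.
#' @param seeds Integer vector; one run per seed.
#' @param n_syn Synapses per direction.
#' @param w0 Initial weight.
#' @param rate_hz Induced rate within the 10 ms windows (Hz).
#' @param window_ms,silence_ms Window and silence durations (ms).
#' @param n_cycles Number of cycles.
#' @param plasticity,synapse,neuron Parameter objects.
#' @return Tibble with one row per seed: mean weights per direction before
#'   and after, and the `label`.
#' @export
protocol_temporal_order <- function(location = c("prox", "dist"),
                                    seeds = 1:5,
                                    n_syn = 10, w0 = 0.5, rate_hz = 150,
                                    window_ms = 10, silence_ms = 250,
                                    n_cycles = 10,
                                    plasticity = plasticity_params(),
                                    synapse = synapse_params(),
                                    neuron = neuron_params(n_dendrites = 2)) {
  location <- match.arg(location)
  cycle <- 2 * window_ms + silence_ms
  purrr::map_dfr(seeds, function(sd) {
    set.seed(as.integer(sd))
    fs <- purrr::map_dfr(seq_len(n_cycles) - 1, function(cyc) {
      t0 <- cyc * cycle
      dplyr::bind_rows(
        tibble::tibble(
          time_ms = t0 + poisson_train(rate_hz, window_ms, dt = neuron$dt),
          neuron = 1L
        ),
        tibble::tibble(
          time_ms = t0 + window_ms +
            poisson_train(rate_hz, window_ms, dt = neuron$dt),
          neuron = 2L
        )
      )
    })
    syns <- tibble::tibble(
      pre_kind = "neuron",
      pre = rep(1:2, each = n_syn),
      post = rep(2:1, each = n_syn),
      dend = 1L, loc = location, w = w0, plastic = TRUE
    )
    cc <- circuit(
      n_neurons = 2, synapses = syns,
      neuron = neuron, synapse = synapse, plasticity = plasticity
    )
    sim <- run_sim(cc, n_cycles * cycle,
      forced_spikes = fs, seed = sd,
      record_weights_every = 1e6
    )
    w_after <- sim$synapses$w
    is12 <- sim$synapses$pre == 1
    tibble::tibble(
      seed = sd, location = location,
      w12_before = w0, w21_before = w0,
      w12_after = mean(w_after[is12]),
      w21_after = mean(w_after[!is12]),
      label = classify_connectivity(
        w0, w_after[is12], w0, w_after[!is12]
      )
    )
  })
}

#' Single-cell association and overwriting protocol
#'
#' One reduced neuron receives two pools of synapses, clustered on two
#' different dendrites at the stated compartment kind, with weights starting
#' at the upper bound. The pools are activated in alternation (Poisson at
#' `rate_hz` for `event_ms`, separated by `gap_ms`); after every
#' `joint_every` single-pool activations both pools are activated
#' simultaneously, and whether that joint event still evokes a somatic
#' spike is recorded. A coloured noise current (mean 35 pA, s.d. 3.5 pA by
#' default) keeps the soma fluctuating. Proximally clustered pools lose
#' their weights (the activations depress and eventually fail to reach
#' threshold); distally clustered pools are maintained by dendritic
#' potentiation.
#'
#' @param location `"prox"` or `"dist"`.
#' @param n_joint Number of joint events to simulate (the run length is
#'   `n_joint * (joint_every + 1)` activation slots).
#' @param pool_size Synapses per pool.
#' @param w0 Initial weight (upper bound by default).
#' @param rate_hz,event_ms,gap_ms Activation parameters.
#' @param joint_every Single activations between joint events.
#' @param seed Integer seed.
#' @param noise Somatic noise; defaults to the association-protocol values.
#' @param plasticity,synapse,neuron Parameter objects.
#' @return A list of class `"dendplast_association"` with `pool_weights`
#'   (tibble: `time_ms`, `pool`, `mean_w`), `joint_events` (tibble:
#'   `time_ms`, `spiked`), `location` and the full `sim`.
#' @export
protocol_single_cell_association <- function(location = c("prox", "dist"),
                                             n_joint = 3,
                                             pool_size = 4, w0 = 1,
                                             rate_hz = 40, event_ms = 50,
                                             gap_ms = 150, joint_every = 20,
                                             seed = 1,
                                             noise = noise_params(
                                               mean = 35, sd = 3.5,
                                               tau = 20, form = "fig5"
                                             ),
                                             plasticity = plasticity_params(),
                                             synapse = synapse_params(),
                                             neuron = neuron_params(
                                               n_dendrites = 2
                                             )) {
  location <- match.arg(location)
  set.seed(as.integer(seed))
  period <- event_ms + gap_ms
  slots_per_block <- joint_every + 1
  n_slots <- n_joint * slots_per_block
  pool_of_slot <- rep(c(rep(1:2, joint_every / 2), 3L), n_joint)
  syns <- tibble::tibble(
    pre_kind = "input", pre = seq_len(2 * pool_size), post = 1L,
    dend = rep(1:2, each = pool_size),
    loc = location, w = w0, plastic = TRUE
  )
  events <- purrr::map_dfr(seq_len(n_slots), function(sl) {
    ids <- switch(pool_of_slot[sl],
      seq_len(pool_size),
      pool_size + seq_len(pool_size),
      seq_len(2 * pool_size)
    )
    tibble::tibble(
      onset_ms = (sl - 1) * period, rate_hz = rate_hz,
      duration_ms = event_ms, input_ids = list(ids)
    )
  })
  spikes <- schedule_input_spikes(events, dt = neuron$dt)
  cc <- circuit(
    n_neurons = 1, synapses = syns,
    neuron = neuron, synapse = synapse, plasticity = plasticity,
    noise = noise
  )
  sim <- run_sim(cc, n_slots * period,
    input_spikes = spikes, seed = seed,
    record_weights_every = period
  )
  pool_weights <- sim$weights |>
    dplyr::mutate(pool = ifelse(.data$syn_id <= pool_size, "A", "B")) |>
    dplyr::group_by(.data$time_ms, .data$pool) |>
    dplyr::summarise(mean_w = mean(.data$w), .groups = "drop")
  joint_onsets <- ((which(pool_of_slot == 3L)) - 1) * period
  joint_events <- tibble::tibble(
    time_ms = joint_onsets,
    spiked = vapply(joint_onsets, function(t0) {
      any(sim$spikes$time_ms >= t0 & sim$spikes$time_ms < t0 + event_ms)
    }, logical(1))
  )
  structure(
    list(
      pool_weights = pool_weights, joint_events = joint_events,
      location = location, sim = sim, seed = seed
    ),
    class = "dendplast_association"
  )
}

# schedule of randomly selected activation targets on a fixed event grid
random_event_schedule <- function(n_events, cycle_ms, choose_target) {
  purrr::map_dfr(seq_len(n_events) - 1, function(ev) {
    tgt <- choose_target()
    if (is.null(tgt)) {
      return(NULL)
    }
    tibble::tibble(onset_ms = ev * cycle_ms, target = tgt)
  })
}

input_ids_of <- function(neurons, n_input) {
  as.integer(outer(seq_len(n_input), (neurons - 1) * n_input, `+`))
}

#' Block-wise weight summaries of a network simulation
#'
#' Joins the recorded weight snapshots with the connectivity table and
#' averages the plastic weights per (presynaptic feature, postsynaptic
#' feature, placement) block.
#'
#' @param sim A [run_sim()] result from a [build_network()] circuit.
#' @param net The network the simulation was run on.
#' @return Tibble with `time_ms`, `pre_feature`, `post_feature`, `loc`,
#'   `mean_w`, `n_syn`.
#' @export
weight_blocks <- function(sim, net) {
  map <- net$synapses |>
    dplyr::filter(.data$plastic) |>
    dplyr::transmute(
      .data$syn_id,
      pre_feature = net$feature_of[.data$pre],
      post_feature = net$feature_of[.data$post],
      loc = .data$loc
    )
  sim$weights |>
    dplyr::inner_join(map, by = "syn_id") |>
    dplyr::group_by(
      .data$time_ms, .data$pre_feature, .data$post_feature, .data$loc
    ) |>
    dplyr::summarise(
      mean_w = mean(.data$w), n_syn = dplyr::n(), .groups = "drop"
    )
}

#' Feature-network memory-retention protocol
#'
#' A population of neurons divided into feature groups, all-to-all connected
#' with weights at the upper bound, is driven by brief strong activations of
#' one randomly chosen feature at a time (Poisson input at `event_rate_hz`
#' for `event_ms`, one event per `cycle_ms`). Proximal weights between
#' features depress away while distal between-feature weights, protected by
#' clustered NMDA plateaus, remain close to their initial value.
#'
#' @param duration_s Simulated seconds.
#' @param n_neurons,n_features Network size (neurons split evenly).
#' @param event_rate_hz,event_ms,cycle_ms Activation event parameters.
#' @param a_inhib Somatic inhibition scale (nS).
#' @param w_init Initial recurrent weight.
#' @param seed Integer seed.
#' @param record_every_s Weight-recording cadence (s).
#' @param neuron,synapse,plasticity,noise Parameter objects; noise defaults
#'   to mean 150 pA, s.d. 15 pA.
#' @return A list of class `"dendplast_memory"`: `blocks` (time-resolved
#'   block summary from [weight_blocks()]), `block_summary` (final-time
#'   within/between means per placement), `net`, `sim`.
#' @export
protocol_feature_network <- function(duration_s = 20,
                                     n_neurons = 40, n_features = 4,
                                     event_rate_hz = 350, event_ms = 10,
                                     cycle_ms = 260,
                                     a_inhib = 0.125, w_init = 1,
                                     seed = 1, record_every_s = 1,
                                     neuron = neuron_params(),
                                     synapse = synapse_params(),
                                     plasticity = plasticity_params(),
                                     noise = noise_params(
                                       mean = 150, sd = 15,
                                       tau = 20, form = "main_text"
                                     )) {
  set.seed(as.integer(seed))
  feats <- split(
    seq_len(n_neurons),
    rep(seq_len(n_features), each = n_neurons / n_features)
  )
  spec <- network_spec(
    n_neurons = n_neurons, features = feats,
    w_init = w_init, a_inhib = a_inhib, seed = seed
  )
  net <- build_network(spec,
    neuron = neuron, synapse = synapse,
    plasticity = plasticity, noise = noise
  )
  n_events <- floor(duration_s * 1000 / cycle_ms)
  sched <- random_event_schedule(
    n_events, cycle_ms,
    function() sample.int(n_features, 1)
  )
  if (nrow(sched) == 0) {
    sched <- tibble::tibble(onset_ms = numeric(0), target = integer(0))
  }
  events <- sched |>
    dplyr::mutate(
      rate_hz = event_rate_hz, duration_ms = event_ms,
      input_ids = purrr::map(.data$target, function(f) {
        input_ids_of(feats[[f]], spec$n_input_synapses)
      })
    )
  spikes <- schedule_input_spikes(events, dt = neuron$dt)
  sim <- run_sim(net, duration_s * 1000,
    input_spikes = spikes, seed = seed,
    record_weights_every = record_every_s * 1000,
    record_gate = TRUE
  )
  blocks <- weight_blocks(sim, net)
  final <- blocks |>
    dplyr::filter(.data$time_ms == max(.data$time_ms)) |>
    dplyr::mutate(
      kind = ifelse(.data$pre_feature == .data$post_feature,
        "within", "between"
      )
    ) |>
    dplyr::group_by(.data$loc, .data$kind) |>
    dplyr::summarise(mean_w = mean(.data$mean_w), .groups = "drop")
  structure(
    list(
      blocks = blocks, block_summary = final,
      schedule = sched, net = net, sim = sim, seed = seed
    ),
    class = "dendplast_memory"
  )
}

#' Overlapping-association retention protocol
#'
#' A network whose features form two associative memories sharing some
#' features. Recurrent weights start at the lower bound. In each phase one
#' memory is activated with high probability and the other rarely
#' (probabilities per cycle; the remainder of the probability mass is
#' silence). The first phase imprints memory 1; the reversed phase imprints
#' memory 2 and erodes the proximal synapses from the shared features onto
#' memory-1-only features, while the corresponding distal synapses, driven
#' by clustered plateaus, are retained.
#'
#' @param phase_s Vector of phase durations (s).
#' @param probs List (one element per phase) of two activation
#'   probabilities per cycle, `c(p_assoc1, p_assoc2)`; their sum must not
#'   exceed 1.
#' @param n_neurons Number of neurons (divided into 6 features of equal
#'   size; features 3 and 4 are shared between the two associations).
#' @param a_inhib Somatic inhibition scale (nS).
#' @param w_init Initial recurrent weight (lower bound by default).
#' @param event_rate_hz,event_ms,cycle_ms Activation event parameters.
#' @param seed Integer seed.
#' @param neuron,synapse,plasticity,noise Parameter objects.
#' @return A `"dendplast_memory"` list: `blocks`, `phase_summary` (per
#'   phase end: mean weight from shared to unshared features per
#'   association and placement), `net`, `sim`.
#' @export
protocol_two_associations <- function(phase_s = c(10, 10, 10),
                                      probs = list(
                                        c(0.90, 0.09),
                                        c(0.09, 0.90),
                                        c(0.90, 0.09)
                                      ),
                                      n_neurons = 60,
                                      a_inhib = 0.100, w_init = 0.01,
                                      event_rate_hz = 350, event_ms = 10,
                                      cycle_ms = 260,
                                      seed = 1,
                                      neuron = neuron_params(),
                                      synapse = synapse_params(),
                                      plasticity = plasticity_params(),
                                      noise = noise_params(
                                        mean = 150, sd = 15,
                                        tau = 20, form = "main_text"
                                      )) {
  stopifnot(length(phase_s) == length(probs))
  if (any(vapply(probs, sum, numeric(1)) > 1)) {
    stop("protocol_two_associations: activation probabilities sum > 1",
      call. = FALSE
    )
  }
  set.seed(as.integer(seed))
  n_feat <- 6L
  feats <- split(
    seq_len(n_neurons),
    rep(seq_len(n_feat), each = n_neurons / n_feat)
  )
  assoc <- list(1:4, 3:6) # features 3, 4 shared
  spec <- network_spec(
    n_neurons = n_neurons, features = feats, associations = assoc,
    w_init = w_init, a_inhib = a_inhib, seed = seed
  )
  net <- build_network(spec,
    neuron = neuron, synapse = synapse,
    plasticity = plasticity, noise = noise
  )
  phase_ms <- phase_s * 1000
  phase_end <- cumsum(phase_ms)
  sched <- purrr::map_dfr(seq_along(phase_s), function(ph) {
    n_events <- floor(phase_ms[ph] / cycle_ms)
    off <- c(0, phase_end)[ph]
    p <- probs[[ph]]
    purrr::map_dfr(seq_len(n_events) - 1, function(ev) {
      u <- stats::runif(1)
      tgt <- if (u < p[1]) 1L else if (u < p[1] + p[2]) 2L else NA_integer_
      if (is.na(tgt)) {
        return(NULL) # leftover probability mass: a silent cycle
      }
      tibble::tibble(onset_ms = off + ev * cycle_ms, target = tgt)
    })
  })
  if (nrow(sched) == 0) {
    sched <- tibble::tibble(onset_ms = numeric(0), target = integer(0))
    spikes <- NULL
  } else {
    events <- sched |>
      dplyr::mutate(
        rate_hz = event_rate_hz, duration_ms = event_ms,
        input_ids = purrr::map(.data$target, function(a) {
          input_ids_of(
            unlist(feats[assoc[[a]]], use.names = FALSE),
            spec$n_input_synapses
          )
        })
      )
    spikes <- schedule_input_spikes(events, dt = neuron$dt)
  }
  sim <- run_sim(net, sum(phase_ms),
    input_spikes = spikes, seed = seed,
    record_weights_every = 1000
  )
  blocks <- weight_blocks(sim, net)
  shared <- 3:4
  only1 <- 1:2
  only2 <- 5:6
  phase_summary <- purrr::map_dfr(seq_along(phase_s), function(ph) {
    blocks |>
      dplyr::filter(.data$time_ms == phase_end[ph]) |>
      dplyr::filter(.data$pre_feature %in% shared) |>
      dplyr::mutate(
        assoc = dplyr::case_when(
          .data$post_feature %in% only1 ~ "assoc1_only",
          .data$post_feature %in% only2 ~ "assoc2_only",
          TRUE ~ NA_character_
        )
      ) |>
      dplyr::filter(!is.na(.data$assoc)) |>
      dplyr::group_by(.data$assoc, .data$loc) |>
      dplyr::summarise(mean_w = mean(.data$mean_w), .groups = "drop") |>
      dplyr::mutate(phase = ph, time_s = phase_end[ph] / 1000)
  })
  structure(
    list(
      blocks = blocks, phase_summary = phase_summary,
      schedule = sched, net = net, sim = sim, seed = seed
    ),
    class = "dendplast_memory"
  )
}
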