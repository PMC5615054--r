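#' Specify a recurrent feature network
#'
#' Describes a population of reduced neurons grouped into features (sets of
#' co-activated neurons), all-to-all connected by plastic synapses, with a
#' stated fraction of connections placed on distal compartments. Distal
#' connections originating from one feature always converge onto the same
#' distal compartment of the postsynaptic neuron, which is what allows
#' feature-specific NMDA plateaus. Each neuron additionally carries
#' non-plastic input synapses (uniformly over proximal compartments) used to
#' drive it, and a somatic feedback-inhibition current proportional to the
#' filtered spike count of its presynaptic neighbours.
#'
#' @param n_neurons Number of neurons.
#' @param features List of integer vectors partitioning `1:n_neurons` into
#'   feature groups.
#' @param associations Optional list of integer vectors of feature indices;
#'   features may belong to several associations.
#' @param frac_distal Fraction of recurrent connections placed distally.
#' @param n_input_synapses Non-plastic input synapses per neuron.
#' @param w_init Initial recurrent weight (`w_max` or `w_min` depending on
#'   the experiment).
#' @param w_input Fixed weight of the input synapses.
#' @param a_inhib Inhibition scale (nS; 0.125 for the four-feature network,
#'   0.100 for the overlapping-association network).
#' @param e_gaba GABA reversal potential (mV).
#' @param tau_inhib Decay time constant of the presynaptic spike filter (ms).
#' @param tau_rise Rise time constant of the inhibitory conductance (ms).
#' @param seed Integer seed making the wiring reproducible.
#' @return A list of class `"network_spec"`.
#' @export
#' @examples
#' spec <- network_spec(40, features = split(1:40, rep(1:4, each = 10)),
#'                      w_init = 1, seed = 1)
network_spec <- function(n_neurons, features, associations = NULL,
                         frac_distal = 0.5, n_input_synapses = 50,
                         w_init = 1, w_input = 1,
                         a_inhib = 0.125, e_gaba = -75,
                         tau_inhib = 30, tau_rise = 2, seed = 1) {
  features <- lapply(features, as.integer)
  all_ids <- sort(unname(unlist(features)))
  if (!identical(all_ids, seq_len(n_neurons))) {
    stop("network_spec: `features` must partition 1:n_neurons", call. = FALSE)
  }
  if (frac_distal < 0 || frac_distal > 1) {
    stop("network_spec: `frac_distal` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_neurons = as.integer(n_neurons), features = features,
      associations = associations, frac_distal = frac_distal,
      n_input_synapses = as.integer(n_input_synapses),
      w_init = w_init, w_input = w_input,
      a_inhib = a_inhib, e_gaba = e_gaba,
      tau_inhib = tau_inhib, tau_rise = tau_rise,
      seed = as.integer(seed)
    ),
    class = "network_spec"
  )
}

#' Assemble a simulatable circuit from a synapse table
#'
#' Low-level constructor used by all protocols. A circuit is a set of
#' reduced neurons plus a synapse table; [build_network()] is the high-level
#' front end for feature networks.
#'
#' The synapse table needs one row per synapse with columns `pre_kind`
#' (`"neuron"` for recurrent synapses, `"input"` for externally driven
#' ones), `pre` (presynaptic neuron id, or input-source id), `post`
#' (postsynaptic neuron), `dend` (dendrite index), `loc` (`"prox"` or
#' `"dist"`), `w` (initial weight) and `plastic` (logical).
#'
#' @param n_neurons Number of neurons.
#' @param synapses Synapse tibble (see Details).
#' @param neuron,synapse,plasticity,noise Parameter objects.
#' @param inhibition `NULL` for none, or a list with `a_inhib` (nS),
#'   `e_gaba`, `tau_inhib`, `tau_rise` (ms).
#' @param distal_gain_recurrent Should recurrent synapses at distal
#'   compartments also receive the distal current gain? (The gain is treated
#'   as a property of the compartment, so the default is `TRUE`.)
#' @return A list of class `"dendplast_circuit"`.
#' @export
circuit <- function(n_neurons, synapses,
                    neuron = neuron_params(),
                    synapse = synapse_params(),
                    plasticity = plasticity_params(),
                    noise = noise_params(),
                    inhibition = NULL,
                    distal_gain_recurrent = TRUE) {
  synapses <- tibble::as_tibble(synapses)
  needed <- c("pre_kind", "pre", "post", "dend", "loc", "w", "plastic")
  if (!all(needed %in% names(synapses))) {
    stop("circuit: synapse table must have columns ",
      paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(synapses$loc %in% c("prox", "dist"))) {
    stop("circuit: `loc` must be 'prox' or 'dist'", call. = FALSE)
  }
  if (any(synapses$dend < 1 | synapses$dend > neuron$n_dendrites)) {
    stop("circuit: dendrite index out of range", call. = FALSE)
  }
  if (any(synapses$post < 1 | synapses$post > n_neurons)) {
    stop("circuit: postsynaptic neuron out of range", call. = FALSE)
  }
  synapses$syn_id <- seq_len(nrow(synapses))
  structure(
    list(
      n_neurons = as.integer(n_neurons),
      synapses = synapses,
      neuron = neuron, synapse = synapse,
      plasticity = plasticity, noise = noise,
      inhibition = inhibition,
      distal_gain_recurrent = isTRUE(distal_gain_recurrent)
    ),
    class = "dendplast_circuit"
  )
}

#' Build an all-to-all plastic network from a specification
#'
#' Every ordered neuron pair receives exactly one plastic synapse. A fraction
#' `frac_distal` of them (exact, drawn without replacement) is placed on
#' distal compartments; the distal synapses arriving from one feature share a
#' single distal compartment per postsynaptic neuron (one dendrite drawn per
#' feature and postsynaptic neuron, distinct across features). Proximal
#' placements draw their dendrite uniformly. Input synapses are non-plastic
#' and spread uniformly over proximal compartments. The construction is
#' deterministic given `spec$seed`.
#'
#' @param spec A [network_spec()].
#' @param neuron,synapse,plasticity Parameter objects; the default neuron has
#'   15 dendrites.
#' @param noise A [noise_params()]; the network default emulates somatic
#'   background drive with mean 150 pA, s.d. 15 pA.
#' @return A `"dendplast_circuit"` with the feature map attached
#'   (`$features`, `$associations`) and the connectivity accessible through
#'   `$synapses`.
#' @export
#' @examples
#' spec <- network_spec(8, features = split(1:8, rep(1:2, each = 4)),
#'                      n_input_synapses = 5, w_init = 1, seed = 42)
#' net <- build_network(spec, neuron = neuron_params(n_dendrites = 4))
#' dplyr::count(net$synapses, pre_kind, loc)
build_network <- function(spec,
                          neuron = neuron_params(),
                          synapse = synapse_params(),
                          plasticity = plasticity_params(),
                          noise = noise_params(
                            mean = 150, sd = 15,
                            tau = 20, form = "main_text"
                          )) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n_neurons
  n_feat <- length(spec$features)
  n_dend <- neuron$n_dendrites
  if (n_feat > n_dend) {
    stop("build_network: more features (", n_feat, ") than distal ",
      "compartments per neuron (", n_dend, "); distal clustering needs ",
      "one dendrite per feature",
      call. = FALSE
    )
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  feature_of <- integer(n)
  for (f in seq_along(spec$features)) feature_of[spec$features[[f]]] <- f

  withr_seed({
    pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
    pairs <- pairs[pairs$pre != pairs$post, ]
    m <- nrow(pairs)
    n_distal <- round(spec$frac_distal * m)
    distal_rows <- sample.int(m, n_distal)
    loc <- rep("prox", m)
    loc[distal_rows] <- "dist"
    # one distal cluster dendrite per (postsynaptic neuron, presynaptic
    # feature), distinct across features within a neuron
    cluster_dend <- t(vapply(
      seq_len(n), function(i) sample.int(n_dend, n_feat),
      integer(n_feat)
    ))
    dend <- integer(m)
    is_d <- loc == "dist"
    dend[is_d] <- cluster_dend[cbind(
      pairs$post[is_d],
      feature_of[pairs$pre[is_d]]
    )]
    dend[!is_d] <- sample.int(n_dend, sum(!is_d), replace = TRUE)
    rec <- tibble::tibble(
      pre_kind = "neuron", pre = pairs$pre, post = pairs$post,
      dend = dend, loc = loc, w = spec$w_init, plastic = TRUE
    )
    inp <- tibble::tibble(
      pre_kind = "input",
      pre = seq_len(n * spec$n_input_synapses),
      post = rep(seq_len(n), each = spec$n_input_synapses),
      dend = sample.int(n_dend, n * spec$n_input_synapses, replace = TRUE),
      loc = "prox", w = spec$w_input, plastic = FALSE
    )
  })
  cc <- circuit(
    n_neurons = n,
    synapses = dplyr::bind_rows(rec, inp),
    neuron = neuron, synapse = synapse, plasticity = plasticity,
    noise = noise,
    inhibition = list(
      a_inhib = spec$a_inhib, e_gaba = spec$e_gaba,
      tau_inhib = spec$tau_inhib, tau_rise = spec$tau_rise
    )
  )
  cc$features <- spec$features
  cc$associations <- spec$associations
  cc$feature_of <- feature_of
  cc$spec <- spec
  cc
}

#' One step of the somatic feedback-inhibition current
#'
#' The spikes of a neuron's presynaptic neighbours are low-pass filtered
#' with `tau_inhib` (`e_in`, which jumps by one per spike), then passed
#' through a rise filter with `tau_rise` (`g_in`). The inhibitory current is
#' `-a_inhib * g_in * (u_soma - e_gaba)`: hyperpolarising whenever the soma
#' sits above the GABA reversal.
#'
#' @param state List with numeric `e_in` and `g_in` (per neuron).
#' @param presyn_spikes Number of presynaptic spikes this step (per neuron).
#' @param u_soma Somatic voltage (mV, per neuron).
#' @param dt Step (ms).
#' @param inhibition List with `a_inhib` (nS), `e_gaba`, `tau_inhib`,
#'   `tau_rise`.
#' @return List with updated `state` and the `current` (pA, per neuron).
#' @export
inhibition_step <- function(state, presyn_spikes, u_soma, dt, inhibition) {
  e_in <- state$e_in * exp(-dt / inhibition$tau_inhib) + presyn_spikes
  g_in <- e_in + (state$g_in - e_in) * exp(-dt / inhibition$tau_rise)
  list(
    state = list(e_in = e_in, g_in = g_in),
    current = -inhibition$a_inhib * g_in * (u_soma - inhibition$e_gaba)
  )
}

#' @export
print.dendplast_circuit <- function(x, ...) {
  cat(
    "<dendplast_circuit>", x$n_neurons, "neuron(s),",
    x$neuron$n_dendrites, "dendrites each,",
    nrow(x$synapses), "synapses (",
    sum(x$synapses$plastic), "plastic ),",
    if (is.null(x$inhibition)) "no inhibition" else "with inhibition", "\n"
  )
  invisible(x)
}

#' Read or write a synapse table as delimited text
#'
#' @param synapses A synapse tibble (see [circuit()]).
#' @param path File path (tab-separated).
#' @return `write_synapses()` returns `path` invisibly; `read_synapses()`
#'   the tibble.
#' @export
write_synapses <- function(synapses, path) {
  utils::write.table(synapses, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_synapses
#' @export
read_synapses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$plastic <- as.logical(df$plastic)
  tibble::as_tibble(df)
}
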