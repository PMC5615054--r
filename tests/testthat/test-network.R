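four_feature_spec <- function(n = 12, k = 4, seed = 5, ...) {
  network_spec(
    n_neurons = n, features = split(seq_len(n), rep(seq_len(k), each = n / k)),
    n_input_synapses = 5, w_init = 1, seed = seed, ...
  )
}

test_that("build_network lays out the stated connectivity", {
  spec <- four_feature_spec()
  net <- build_network(spec, neuron = neuron_params(n_dendrites = 6))
  rec <- dplyr::filter(net$synapses, .data$pre_kind == "neuron")
  expect_equal(nrow(rec), 12 * 11) # one synapse per ordered pair
  expect_true(all(rec$plastic))
  expect_equal(sum(rec$loc == "dist"), round(0.5 * 12 * 11))
  expect_false(any(rec$pre == rec$post))
  inp <- dplyr::filter(net$synapses, .data$pre_kind == "input")
  expect_equal(nrow(inp), 12 * 5)
  expect_true(all(inp$loc == "prox"))
  expect_false(any(inp$plastic))
})

test_that("distal synapses from one feature share one compartment per
           target", {
  net <- build_network(
    four_feature_spec(), neuron = neuron_params(n_dendrites = 6)
  )
  rec <- dplyr::filter(
    net$synapses, .data$pre_kind == "neuron", .data$loc == "dist"
  )
  rec$pre_feature <- net$feature_of[rec$pre]
  combos <- dplyr::summarise(
    dplyr::group_by(rec, .data$post, .data$pre_feature),
    n_dend = dplyr::n_distinct(.data$dend), .groups = "drop"
  )
  expect_true(all(combos$n_dend == 1))
  # distinct features use distinct cluster compartments within a neuron
  per_post <- dplyr::summarise(
    dplyr::group_by(rec, .data$post),
    n_feat = dplyr::n_distinct(.data$pre_feature),
    n_dend = dplyr::n_distinct(.data$dend), .groups = "drop"
  )
  expect_true(all(per_post$n_dend == per_post$n_feat))
})

test_that("network build is deterministic and capacity-checked", {
  a <- build_network(four_feature_spec(seed = 9))
  b <- build_network(four_feature_spec(seed = 9))
  expect_identical(a$synapses, b$synapses)
  c <- build_network(four_feature_spec(seed = 10))
  expect_false(identical(a$synapses, c$synapses))
  expect_error(
    build_network(
      four_feature_spec(), neuron = neuron_params(n_dendrites = 3)
    ),
    "more features"
  )
  expect_error(
    network_spec(8, features = list(1:3, 4:8, 2:3)), "partition"
  )
  expect_error(network_spec(8, features = list(1:8), frac_distal = 2), "frac")
})

test_that("inhibition filters follow their double-exponential closed form", {
  inh <- list(a_inhib = 0.125, e_gaba = -75, tau_inhib = 30, tau_rise = 2)
  st <- list(e_in = 0, g_in = 0)
  # no spikes ever: zero current
  r <- inhibition_step(st, 0, -55, 0.25, inh)
  expect_equal(r$current, 0)
  # reversal: no current at E_GABA regardless of conductance
  r2 <- inhibition_step(list(e_in = 5, g_in = 5), 0, -75, 0.25, inh)
  expect_equal(r2$current, 0)
  # one spike: E_in jumps by 1, decays e-fold in 30 ms; g_in rises in ~2 ms
  st <- inhibition_step(st, 1, -55, 0.25, inh)$state
  expect_equal(st$e_in, 1)
  e_series <- g_series <- numeric(200)
  for (k in 1:200) {
    st <- inhibition_step(st, 0, -55, 0.25, inh)$state
    e_series[k] <- st$e_in
    g_series[k] <- st$g_in
  }
  expect_equal(e_series[120], exp(-120 * 0.25 / 30), tolerance = 1e-6)
  expect_equal(which.max(g_series) * 0.25, 7, tolerance = 2.5)
  expect_lt(abs(max(g_series) -
    (30 / (30 - 2)) * ((2 / 30)^(2 / (30 - 2)) - (2 / 30)^(30 / (30 - 2)))),
    0.25)
  # hyperpolarising above the reversal
  r3 <- inhibition_step(list(e_in = 3, g_in = 3), 0, -55, 0.25, inh)
  expect_lt(r3$current, 0)
})

test_that("an empty schedule leaves a noiseless network silent and
           unchanged", {
  net <- build_network(four_feature_spec(), noise = noise_params())
  sim <- run_sim(net, 300, seed = 3)
  expect_equal(nrow(sim$spikes), 0)
  expect_equal(sim$synapses$w, net$synapses$w)
})

test_that("network replay is bit-identical under equal seeds", {
  net <- build_network(four_feature_spec())
  ids <- as.integer(outer(1:5, (1:6 - 1) * 5, `+`))
  set.seed(77)
  ev <- tibble::tibble(
    onset_ms = c(10, 150), rate_hz = 900, duration_ms = 15,
    input_ids = list(ids, ids)
  )
  spk <- schedule_input_spikes(ev)
  s1 <- run_sim(net, 300, input_spikes = spk, seed = 21)
  s2 <- run_sim(net, 300, input_spikes = spk, seed = 21)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$synapses$w, s2$synapses$w)
  expect_gt(nrow(s1$spikes), 0)
})

test_that("disabling inhibition raises firing under sustained drive", {
  spec <- four_feature_spec(seed = 6)
  net <- build_network(spec)
  net_no <- net
  net_no$inhibition <- NULL
  set.seed(5)
  ids <- as.integer(outer(1:5, (1:12 - 1) * 5, `+`))
  ev <- purrr::map_dfr(0:5, function(e) tibble::tibble(
    onset_ms = e * 50, rate_hz = 200, duration_ms = 40,
    input_ids = list(ids)
  ))
  spk <- schedule_input_spikes(ev)
  with_inh <- run_sim(net, 300, input_spikes = spk, seed = 8)
  without <- run_sim(net_no, 300, input_spikes = spk, seed = 8)
  expect_gt(nrow(without$spikes), nrow(with_inh$spikes))
})

test_that("weight recorders stay within bounds during activity", {
  net <- build_network(four_feature_spec(seed = 2))
  set.seed(12)
  ids <- as.integer(outer(1:5, (1:6 - 1) * 5, `+`))
  ev <- tibble::tibble(
    onset_ms = c(5, 100, 200), rate_hz = 350, duration_ms = 10,
    input_ids = list(ids, ids, ids)
  )
  sim <- run_sim(net, 300,
    input_spikes = schedule_input_spikes(ev),
    seed = 4, record_weights_every = 50
  )
  w <- tidy(sim, "weights")
  expect_true(all(w$w >= 0.01 - 1e-12 & w$w <= 1 + 1e-12))
  pl <- sum(net$synapses$plastic)
  expect_true(all(
    dplyr::count(w, .data$time_ms)$n == pl
  ))
})

test_that("synapse tables round-trip through delimited text", {
  net <- build_network(four_feature_spec())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_synapses(net$synapses, f)
  back <- read_synapses(f)
  expect_equal(nrow(back), nrow(net$synapses))
  expect_equal(back$w, net$synapses$w)
  expect_equal(back$loc, net$synapses$loc)
  expect_equal(back$plastic, net$synapses$plastic)
})
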