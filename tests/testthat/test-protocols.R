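test_that("pairing protocol is inert when plasticity amplitudes vanish", {
  off <- plasticity_params(a_ltd = 0, a_ltp = 0)
  r <- protocol_pairing(
    frequencies = c(1, 40), side = "pre_post", plasticity = off
  )
  expect_equal(r$ratio, c(1, 1))
  expect_equal(r$w_final, c(0.5, 0.5))
})

test_that("pairing shows the STDP sign structure at representative
           frequencies", {
  dep <- protocol_pairing(frequencies = 1, side = "post_pre")
  expect_lt(dep$ratio, 1)
  pot <- protocol_pairing(frequencies = 50, side = "pre_post")
  expect_gt(pot$ratio, 1)
})

test_that("rate protocol leaves weights unchanged without spikes", {
  r <- protocol_rate_ltp(rates = 0, location = "prox", n_reps = 1)
  expect_equal(r$mean_w_final, 0.5)
  on <- ltp_onset_rate(r)
  expect_equal(on$onset_rate_hz, Inf)
})

test_that("connectivity classification covers its four cases and ties", {
  expect_equal(classify_connectivity(0.5, 0.9, 0.5, 0.2), "unidirectional_12")
  expect_equal(classify_connectivity(0.5, 0.2, 0.5, 0.9), "unidirectional_21")
  expect_equal(classify_connectivity(0.5, 0.9, 0.5, 0.9), "bidirectional")
  expect_equal(classify_connectivity(0.5, 0.2, 0.5, 0.2), "unconnected")
  # a tie counts as not strengthened
  expect_equal(classify_connectivity(0.5, 0.5, 0.5, 0.5), "unconnected")
  expect_equal(classify_connectivity(0.5, 0.5, 0.5, 0.9), "unidirectional_21")
})

test_that("temporal-order runs are deterministic per seed and classified
           by the rule", {
  r1 <- protocol_temporal_order("prox", seeds = 3, n_cycles = 3)
  r2 <- protocol_temporal_order("prox", seeds = 3, n_cycles = 3)
  expect_identical(r1, r2)
  expect_equal(
    r1$label,
    classify_connectivity(
      r1$w12_before, r1$w12_after, r1$w21_before, r1$w21_after
    )
  )
})

test_that("single-cell association retains distal pools better than
           proximal pools", {
  prox <- protocol_single_cell_association("prox", n_joint = 2, seed = 1)
  dist <- protocol_single_cell_association("dist", n_joint = 2, seed = 1)
  last_w <- function(res) {
    w <- res$pool_weights
    mean(w$mean_w[w$time_ms == max(w$time_ms)])
  }
  expect_gt(last_w(dist), last_w(prox) + 0.02)
  expect_gt(last_w(dist), 0.97) # distal pools stay near the upper bound
  expect_lt(last_w(prox), 1) # proximal pools lose weight
  # joint-event outcomes are recorded for every joint activation
  expect_equal(nrow(dist$joint_events), 2)
  expect_type(dist$joint_events$spiked, "logical")
  # without activations, nothing changes
  none <- protocol_single_cell_association("prox",
    n_joint = 1, rate_hz = 0, seed = 1,
    noise = noise_params(mean = 0, sd = 0, tau = 20, form = "fig5")
  )
  w <- none$pool_weights
  expect_true(all(w$mean_w == 1))
})

test_that("feature-network protocol emits its realized schedule and block
           series", {
  fn <- protocol_feature_network(
    duration_s = 2, n_neurons = 12, n_features = 4, seed = 2,
    neuron = neuron_params(n_dendrites = 5)
  )
  expect_s3_class(fn, "dendplast_memory")
  expect_equal(nrow(fn$schedule), floor(2000 / 260))
  expect_true(all(fn$schedule$target %in% 1:4))
  expect_true(all(c("prox", "dist") %in% fn$block_summary$loc))
  expect_true(all(fn$blocks$mean_w >= 0.01 & fn$blocks$mean_w <= 1))
})

test_that("two-association protocol respects probabilities and silence", {
  # all probabilities zero: no events, weights pinned at the lower bound
  ta <- protocol_two_associations(
    phase_s = 1, probs = list(c(0, 0)), n_neurons = 12, seed = 3,
    neuron = neuron_params(n_dendrites = 6),
    noise = noise_params(mean = 0, sd = 0, tau = 20)
  )
  expect_equal(nrow(ta$schedule), 0)
  expect_true(all(ta$sim$synapses$w[ta$sim$synapses$plastic] == 0.01))
  expect_error(
    protocol_two_associations(
      phase_s = 1, probs = list(c(0.8, 0.4)), n_neurons = 12
    ),
    "sum > 1"
  )
})
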