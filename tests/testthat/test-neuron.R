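quiet_circuit <- function(n_dend = 1, ...) {
  circuit(
    n_neurons = 1,
    synapses = tibble::tibble(
      pre_kind = "input", pre = 1, post = 1, dend = 1,
      loc = "prox", w = 0, plastic = FALSE
    ),
    neuron = neuron_params(n_dendrites = n_dend), ...
  )
}

all_comp_trace <- function(n_dend = 1) {
  tibble::tibble(
    neuron = 1,
    compartment = c("soma", rep(c("prox", "dist"), each = n_dend)),
    dend = c(NA, seq_len(n_dend), seq_len(n_dend))
  )
}

test_that("every compartment rests at the leak potential without input", {
  sim <- run_sim(quiet_circuit(3), 200, record_trace = all_comp_trace(3))
  tail_u <- dplyr::filter(tidy(sim, "trace"), time_ms > 150)
  # only the femtoampere-scale exponential current at rest perturbs E_L
  expect_lt(max(abs(tail_u$u_mv + 69)), 1e-3)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("somatic relaxation shows the membrane time constant C/g_L", {
  # +100 pA step: dendrites stay below the soma, so no axial backflow and
  # the soma relaxes with tau_m = 281/40 = 7.025 ms
  sim <- run_sim(quiet_circuit(), 60,
    i_ext = list(soma = 100),
    record_trace = tibble::tibble(
      neuron = 1, compartment = "soma", dend = NA
    )
  )
  tr <- tidy(sim, "trace")
  u_inf <- tr$u_mv[nrow(tr)]
  target <- -69 + (u_inf + 69) * (1 - exp(-1))
  t_fold <- min(tr$time_ms[tr$u_mv >= target])
  expect_equal(t_fold, 281 / 40, tolerance = 0.05)
})

test_that("a forced spike produces the stated clamp sequence", {
  sim <- run_sim(quiet_circuit(), 20,
    forced_spikes = tibble::tibble(time_ms = 5, neuron = 1),
    record_trace = all_comp_trace(1)
  )
  tr <- tidy(sim, "trace")
  soma <- tr[tr$compartment == "soma", ]
  prox <- tr[tr$compartment == "prox", ]
  dist <- tr[tr$compartment == "dist", ]
  # soma held at 30 mV for 1 ms from spike onset, then reset to -55
  held <- soma$time_ms >= 5.25 & soma$time_ms <= 6
  expect_true(all(soma$u_mv[held] == 30))
  expect_equal(sum(soma$u_mv == 30), 4)
  after <- soma$u_mv[soma$time_ms == 6.25]
  expect_lt(abs(after - (-55)), 1)
  # dendritic holds: 10 / -3 mV for 1 ms, delayed to the 0.5 ms boundary
  expect_equal(sum(prox$u_mv == 10), 4)
  expect_equal(sum(dist$u_mv == -3), 4)
  expect_equal(min(prox$time_ms[prox$u_mv == 10]) - 5.25, 0.5)
  expect_equal(sim$realized$bap_delay_ms, 0.5)
  # somatic voltage never exceeds the spike hold value
  expect_lte(max(soma$u_mv), 30)
  expect_equal(nrow(sim$spikes), 1)
})

test_that("spikes re-trigger only outside the hold", {
  sim <- run_sim(quiet_circuit(), 20,
    forced_spikes = tibble::tibble(time_ms = c(5, 5.5, 8), neuron = 1)
  )
  expect_equal(sim$spikes$time_ms, c(5.25, 8.25), tolerance = 1e-9)
})

test_that("constant suprathreshold current gives periodic adapted spiking", {
  sim <- run_sim(quiet_circuit(), 500, i_ext = list(soma = 900))
  isi <- diff(sim$spikes$time_ms)
  expect_gt(nrow(sim$spikes), 5)
  # adaptation: later intervals no shorter than the first ones
  expect_gte(mean(utils::tail(isi, 3)), mean(utils::head(isi, 3)) - 1e-9)
  expect_lt(stats::sd(utils::tail(isi, 5)), 0.5) # settles to a period
})

test_that("halving dt changes a driven subthreshold trajectory < 0.5 mV", {
  mk <- function(dt) {
    cc <- circuit(
      n_neurons = 1,
      synapses = tibble::tibble(
        pre_kind = "input", pre = 1:2, post = 1, dend = 1,
        loc = c("prox", "dist"), w = 0.5, plastic = FALSE
      ),
      neuron = neuron_params(dt = dt, n_dendrites = 1)
    )
    sim <- run_sim(cc, 100,
      input_spikes = tibble::tibble(
        time_ms = c(10, 11, 30, 30.5, 60), input_id = c(1, 1, 2, 2, 2)
      ),
      i_ext = list(soma = 150),
      record_trace = all_comp_trace(1)
    )
    tr <- tidy(sim, "trace")
    tr[tr$time_ms %% 1 < 1e-9, ]
  }
  a <- mk(0.25)
  b <- mk(0.125)
  m <- dplyr::inner_join(
    a, b,
    by = c("time_ms", "compartment", "dend"), suffix = c("_a", "_b")
  )
  expect_gt(nrow(m), 250)
  expect_lt(max(abs(m$u_mv_a - m$u_mv_b)), 0.5)
})

test_that("identical seeds replay identical noisy simulations", {
  cc <- quiet_circuit(noise = noise_params(mean = 100, sd = 30, tau = 20))
  s1 <- run_sim(cc, 200, seed = 11, record_trace = all_comp_trace(1))
  s2 <- run_sim(cc, 200, seed = 11, record_trace = all_comp_trace(1))
  expect_identical(s1$trace$u_mv, s2$trace$u_mv)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- run_sim(cc, 200, seed = 12, record_trace = all_comp_trace(1))
  expect_false(identical(s1$trace$u_mv, s3$trace$u_mv))
})

test_that("engine matches the independent dt/16 Euler reference", {
  # fixed constant-current stimulus on all compartments, subthreshold:
  # the trajectory contract is 0.2 mV against the refined reference
  ref <- ref_neuron_trace(100, n_dend = 1, i_soma = 80, i_prox = 30,
                          i_dist = 20)
  cc <- circuit(
    n_neurons = 1,
    synapses = tibble::tibble(
      pre_kind = "input", pre = 1, post = 1, dend = 1,
      loc = "prox", w = 0, plastic = FALSE
    ),
    neuron = neuron_params(n_dendrites = 1)
  )
  sim <- run_sim(cc, 100,
    i_ext = list(soma = 80, prox = 30, dist = 20),
    record_trace = all_comp_trace(1)
  )
  tr <- tidy(sim, "trace")
  eng <- cbind(
    tr$u_mv[tr$compartment == "soma"],
    tr$u_mv[tr$compartment == "prox"],
    tr$u_mv[tr$compartment == "dist"]
  )
  expect_equal(nrow(eng), nrow(ref))
  expect_lt(max(abs(eng - ref[, c("soma", "prox1", "dist1")])), 0.2)

  # with conductance jumps the agreement is limited by the one-step
  # transient at each event (the jump acts over a whole coarse step)
  ev <- tibble::tibble(
    time_ms = c(10, 10.25, 40, 40.25, 41, 70),
    comp = c("prox", "prox", "dist", "dist", "dist", "prox"),
    dend = 1L, w = c(0.08, 0.08, 0.1, 0.1, 0.1, 0.12)
  )
  ref2 <- ref_neuron_trace(100,
    n_dend = 1, i_soma = 120, i_prox = 50, i_dist = 30, syn_events = ev
  )
  cc2 <- circuit(
    n_neurons = 1,
    synapses = tibble::tibble(
      pre_kind = "input", pre = seq_len(nrow(ev)), post = 1, dend = 1,
      loc = ev$comp, w = ev$w, plastic = FALSE
    ),
    neuron = neuron_params(n_dendrites = 1)
  )
  sim2 <- run_sim(cc2, 100,
    input_spikes = tibble::tibble(
      time_ms = ev$time_ms, input_id = seq_len(nrow(ev))
    ),
    i_ext = list(soma = 120, prox = 50, dist = 30),
    record_trace = all_comp_trace(1)
  )
  tr2 <- tidy(sim2, "trace")
  eng2 <- cbind(
    tr2$u_mv[tr2$compartment == "soma"],
    tr2$u_mv[tr2$compartment == "prox"],
    tr2$u_mv[tr2$compartment == "dist"]
  )
  expect_lt(max(abs(eng2 - ref2[, c("soma", "prox1", "dist1")])), 0.75)
})

test_that("a spike decays cleanly with no runaway re-excitation", {
  sim <- run_sim(quiet_circuit(2), 100,
    forced_spikes = tibble::tibble(time_ms = 5, neuron = 1),
    record_trace = all_comp_trace(2)
  )
  expect_true(all(is.finite(sim$trace$u_mv)))
  expect_lte(max(sim$trace$u_mv), 30)
  expect_equal(nrow(sim$spikes), 1) # no runaway re-triggering
  # all compartments return to rest
  late <- sim$trace$u_mv[sim$trace$time_ms > 80]
  expect_lt(max(abs(late + 69)), 0.1)
})
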