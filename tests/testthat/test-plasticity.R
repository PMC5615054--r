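test_that("traces rest at their fixed points and respond as first-order", {
  p <- plasticity_params()
  u <- rep(-69, 2000)
  tr <- plasticity_trajectory(u, numeric(0), p, w0 = 0.5)
  expect_equal(unique(tr$xbar), 0)
  expect_equal(max(abs(tr$u_minus + 69)), 0)
  expect_equal(unique(tr$w), 0.5) # presynaptic silence: weight constant
  # one presynaptic spike: xbar jumps by x_reset then decays e-fold in tau_x
  tr2 <- plasticity_trajectory(rep(-69, 400), 10, p)
  at <- function(t) tr2$xbar[which.min(abs(tr2$time_ms - t))]
  expect_equal(at(10.25), p$x_reset, tolerance = 0.02)
  expect_equal(at(10.25 + 15), p$x_reset / exp(1), tolerance = 0.02)
  # voltage step: u_plus reaches 63.2% after tau_plus (+ the eps lag)
  us <- c(rep(-69, 40), rep(-49, 800))
  tr3 <- plasticity_trajectory(us, numeric(0), p)
  t0 <- 40 * 0.25 + p$eps
  target <- -69 + 20 * (1 - exp(-1))
  t63 <- min(tr3$time_ms[tr3$u_plus >= target]) - t0
  expect_equal(t63, p$tau_plus, tolerance = 0.02 * p$tau_plus)
})

test_that("rectifiers close below the thresholds", {
  p <- plasticity_params()
  # voltage stays below theta_minus: presynaptic spikes change nothing
  u <- rep(-72, 2000)
  tr <- plasticity_trajectory(u, seq(10, 400, by = 25), p, w0 = 0.5)
  expect_equal(tr$w[nrow(tr)], 0.5)
  # depolarised above theta_minus but below theta_plus and no presynaptic
  # spikes: still nothing
  tr2 <- plasticity_trajectory(rep(-50, 2000), numeric(0), p, w0 = 0.5)
  expect_equal(tr2$w[nrow(tr2)], 0.5)
})

test_that("LTD is linear in the filtered depolarisation above theta_minus", {
  p <- plasticity_params()
  dep <- vapply(c(2, 4, 8), function(d) {
    u <- rep(-69 + d, 2000) # constant depolarisation, filters equilibrate
    tr <- plasticity_trajectory(u, 400, p, w0 = 0.5)
    0.5 - tr$w[nrow(tr)]
  }, numeric(1))
  expect_gt(dep[1], 0)
  expect_equal(dep[2] / dep[1], 2, tolerance = 0.02)
  expect_equal(dep[3] / dep[1], 4, tolerance = 0.02)
})

test_that("LTP is linear in the presynaptic trace", {
  p <- plasticity_params(a_ltd = 0)
  u <- rep(-69, 800)
  u[201:204] <- 10 # one bAP-like event, with prior depolarisation
  u[100:200] <- -55
  pot <- vapply(list(45, c(44.5, 45), c(44, 44.5, 45)), function(ts) {
    tr <- plasticity_trajectory(u, ts, p, w0 = 0.1)
    tr$w[nrow(tr)] - 0.1
  }, numeric(1))
  expect_gt(pot[1], 0)
  expect_equal(pot[2] / pot[1], 2, tolerance = 0.05)
  expect_equal(pot[3] / pot[1], 3, tolerance = 0.08)
})

test_that("weights stay inside the hard bounds under random episodes", {
  p <- plasticity_params()
  set.seed(99)
  for (i in 1:8) {
    u <- random_voltage_episode()
    spikes <- poisson_train(sample(c(5, 20, 80), 1), 1000)
    tr <- plasticity_trajectory(u, spikes, p, w0 = runif(1, 0.01, 1))
    expect_true(all(tr$w >= p$w_min - 1e-12))
    expect_true(all(tr$w <= p$w_max + 1e-12))
  }
})

test_that("the plateau gate opens only for supra-threshold spans longer
           than a spike", {
  p <- plasticity_params()
  expect_false(nmda_ltp_gate(rep(-69, 100), p)) # rest
  expect_true(nmda_ltp_gate(rep(-10, 30), p)) # 7.5 ms plateau
  expect_false(nmda_ltp_gate(rep(-10, 4), p)) # underfull buffer
  # a 1 ms spike-width excursion can never open the gate
  u <- c(rep(-69, 50), rep(10, 4), rep(-69, 10))
  for (m in 55:64) expect_false(nmda_ltp_gate(u[1:m], p))
  # trajectory-level: gate column matches during a plateau
  u2 <- c(rep(-69, 100), rep(-5, 60), rep(-69, 100))
  tr <- plasticity_trajectory(u2, numeric(0), p)
  gate_on <- tr$time_ms[tr$gate]
  expect_gte(min(gate_on), 100 * 0.25 + p$dltp_lookback)
  expect_equal(sum(tr$gate), 60 - 5) # lookback realised as 5 steps
})

test_that("plateau potentiation uses the reduced dLTP amplitude", {
  # identical plateau, gated rule vs dltp_scale = 1; small amplitude so the
  # weight stays far from the bound and the 0.15 scaling is visible
  p <- plasticity_params(a_ltp = 4e-6, a_ltd = 0)
  p1 <- plasticity_params(a_ltp = 4e-6, a_ltd = 0, dltp_scale = 1)
  u <- c(rep(-69, 100), rep(-5, 400), rep(-69, 100))
  spikes <- seq(26, 120, by = 4)
  w_gated <- plasticity_trajectory(u, spikes, p, w0 = 0.2)
  w_full <- plasticity_trajectory(u, spikes, p1, w0 = 0.2)
  dw_g <- w_gated$w[nrow(w_gated)] - 0.2
  dw_f <- w_full$w[nrow(w_full)] - 0.2
  expect_gt(dw_g, 0)
  expect_lt(dw_g, dw_f) # the gate attenuates potentiation
  # away from the gate-opening transient the attenuation is the stated 0.15
  expect_equal(dw_g / dw_f, 0.15, tolerance = 0.1)
})

test_that("detailed variant filters through u1 without plateau gating", {
  pd <- plasticity_params("detailed")
  u <- c(rep(-69, 100), rep(-5, 200), rep(-69, 100))
  tr <- plasticity_trajectory(u, c(20, 24, 28), pd, w0 = 0.2)
  expect_false(any(tr$gate))
  expect_gt(tr$w[nrow(tr)], 0.2) # plateau still potentiates, ungated
})

test_that("module agrees with the dt/16 scalar reference on random
           episodes", {
  p <- plasticity_params()
  set.seed(2024)
  n_ok <- 0
  for (i in 1:6) {
    u <- random_voltage_episode()
    spikes <- poisson_train(15, 1000)
    w0 <- 0.5
    tr <- plasticity_trajectory(u, spikes, p, w0 = w0)
    w_mod <- tr$w[nrow(tr)]
    w_ref <- ref_plasticity(u, spikes, p, w0 = w0)
    dw_ref <- w_ref - w0
    tol <- 0.01 * max(abs(dw_ref), 0.02)
    expect_lt(abs(w_mod - w_ref), tol)
    n_ok <- n_ok + (abs(dw_ref) > 0.02)
  }
  expect_gt(n_ok, 2) # most episodes produced substantive weight change
})

test_that("engine plasticity matches the trajectory module on a pairing
           run", {
  # record the compartment voltage the engine's rule saw, replay it through
  # plasticity_trajectory, and compare final weights
  cc <- clustered_input_circuit("prox", n_syn = 1, w0 = 0.5)
  pre_t <- c(50, 250, 450)
  post_t <- pre_t + 10
  sim <- run_sim(cc, 600,
    input_spikes = tibble::tibble(time_ms = pre_t, input_id = 1),
    forced_spikes = tibble::tibble(time_ms = post_t, neuron = 1),
    record_trace = tibble::tibble(
      neuron = 1, compartment = "prox", dend = 1
    )
  )
  u <- tidy(sim, "trace")$u_mv
  tr <- plasticity_trajectory(u, pre_t, cc$plasticity, w0 = 0.5)
  expect_equal(sim$synapses$w[1], tr$w[nrow(tr)], tolerance = 1e-10)
})
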