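test_that("rate constants match their closed forms and analytic limits", {
  expect_equal(hh_rate_constants(-10)$alpha_n, 0.1)   # removable singularity
  expect_equal(hh_rate_constants(-25)$alpha_m, 1.0)   # removable singularity
  expect_equal(hh_rate_constants(0)$beta_n, 0.125)
  # continuity across the singular points
  eps <- 1e-5
  expect_equal(hh_rate_constants(-10 + eps)$alpha_n,
               hh_rate_constants(-10 - eps)$alpha_n, tolerance = 1e-4)
  rc <- hh_rate_constants(seq(-120, 60, by = 1))
  expect_true(all(as.matrix(rc[-1]) >= 0))
})

test_that("Nernst potentials: values, antisymmetry, domain errors", {
  expect_equal(nernst_potential(135, 135), 0)
  expect_equal(nernst_potential(2.5, 135), -105.87, tolerance = 1e-3)
  expect_equal(nernst_potential(116, 12), 60.27, tolerance = 1e-3)
  set.seed(21)
  a <- runif(20, 0.5, 200)
  b <- runif(20, 0.5, 200)
  expect_equal(nernst_potential(a, b), -nernst_potential(b, a))
  expect_error(nernst_potential(-1, 10), "positive")
  expect_error(nernst_potential(10, 0), "positive")
})

test_that("membrane currents balance at the calibrated rest", {
  p <- test_cal$params
  ions <- p$ions
  gates <- c(V_N = p$neuron$V_rest, kirdyn:::hh_gates_inf(0))
  cur <- neuron_currents(gates, ions, p$neuron)
  expect_lt(abs(sum(cur)), 1e-9)
  # m = 0 kills the sodium current regardless of voltage
  gates["m"] <- 0
  expect_equal(unname(neuron_currents(gates, ions, p$neuron)[["I_Na"]]), 0)
})

test_that("the calibrated rest is a fixed point of the full model", {
  tr <- run_simulation(protocol("rest"), test_cal)
  expect_lt(max(abs(tr$V_N + 70)), 1e-6)
  expect_lt(max(abs(tr$V_A + 80)), 1e-6)
  expect_lt(max(abs(tr$K_o - 2.5)), 1e-8)
  expect_lt(max(abs(tr$Na_n - 12)), 1e-8)
})

test_that("a single stimulation evokes at least one action potential", {
  spikes <- detect_spikes(test_single)
  expect_gte(length(spikes), 1)
  expect_true(all(spikes > 1000))
  # gating variables stay in [0, 1] along the spiking trajectory
  expect_true(all(test_single$n >= 0 & test_single$n <= 1))
  expect_true(all(test_single$m >= 0 & test_single$m <= 1))
  expect_true(all(test_single$h >= 0 & test_single$h <= 1))
})

test_that("one R-level neuron step matches the compiled step at fixed ions", {
  p <- test_cal$params
  st <- c(V_N = -60, n = 0.4, m = 0.1, h = 0.5)
  out <- step_neuron(st, I_app = 5000, ions = p$ions, params = p$neuron, dt = 0.1)
  # a large depolarising current beats the outward K+ current at -60 mV
  expect_gt(out[["V_N"]], st[["V_N"]])
  # without input the same state repolarises (K+ current dominates)
  out0 <- step_neuron(st, I_app = 0, ions = p$ions, params = p$neuron, dt = 0.1)
  expect_lt(out0[["V_N"]], st[["V_N"]])
  expect_true(all(out[c("n", "m", "h")] >= 0 & out[c("n", "m", "h")] <= 1))
})

test_that("spike detection counts constructed events and respects lockout", {
  expect_length(detect_spikes(rep(-70, 100), 1:100), 0)
  expect_length(detect_spikes(numeric(0)), 0)
  v <- rep(-70, 1000)
  for (s in c(100, 400, 700)) v[s:(s + 10)] <- 10  # three square events
  expect_length(detect_spikes(v, seq_along(v)), 3)
  # events closer than the refractory window merge
  v2 <- rep(-70, 100)
  v2[c(10, 11)] <- 10
  v2[c(12, 13)] <- -25
  v2[c(14, 15)] <- 10
  expect_length(detect_spikes(v2, seq_along(v2), refractory = 10), 1)
})

test_that("membrane noise is reproducible and sized to the calibrated SD", {
  pr <- protocol("rest", noise_sigma = 0.68, seed = 42, horizon_s = 4)
  a <- run_simulation(pr, test_cal)
  b <- run_simulation(pr, test_cal)
  expect_identical(a$V_N, b$V_N)
  s <- sd(a$V_N[a$time > 500])
  expect_gt(s, 0.15)   # ~1 mV peak-to-peak band
  expect_lt(s, 0.35)
  pr$seed <- 43
  expect_false(identical(run_simulation(pr, test_cal)$V_N, a$V_N))
})
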