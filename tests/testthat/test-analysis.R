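test_that("20-80% kinetics is exact on a triangular pulse", {
  time <- seq(0, 6000, by = 1)
  y <- rep(0, length(time))
  ramp <- time >= 2000 & time <= 3000
  y[ramp] <- (time[ramp] - 2000) / 1000          # linear rise over 1000 ms
  fall <- time > 3000 & time <= 4000
  y[fall] <- 1 - (time[fall] - 3000) / 1000      # linear fall over 1000 ms
  d <- tibble::tibble(time = time, y = y)
  k <- kinetics(d, "y", onset_ms = 2000, fit_tau = FALSE)
  expect_equal(k$rise_ms, 600)      # 0.6 x half-width, exact on a ramp
  expect_equal(k$decay_ms, 600)
  expect_equal(k$peak_amplitude, 1)
  expect_equal(k$t_peak_ms, 1000)

  flat <- tibble::tibble(time = time, y = rep(1.3, length(time)))
  expect_error(kinetics(flat, "y", onset_ms = 2000), "no clear transient")
})

test_that("exponential fits are exact without noise, 2%-accurate with 1% noise", {
  time <- seq(0, 10000, by = 2)
  d <- tibble::tibble(time = time, y = 0.4 + 2 * exp(-time / 2000))
  fit <- fit_decay(d, "y", c(0, 10000))
  expect_equal(fit$tau_ms, 2000, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(glance(fit)$quality_ok)

  set.seed(99)
  for (rep in 1:5) {
    dn <- d
    dn$y <- dn$y + rnorm(nrow(d), 0, 0.01 * 2)  # 1% of the amplitude
    fn <- fit_decay(dn, "y", c(0, 10000))
    expect_lt(abs(fn$tau_ms / 2000 - 1), 0.02)
  }

  rising <- tibble::tibble(time = time, y = 1 - exp(-time / 500))
  expect_error(fit_decay(rising, "y", c(0, 4000)), "not decaying")
})

test_that("phase decomposition orders the phases and bounds the buffering", {
  pd <- phase_decomposition(test_single)
  expect_gt(pd$t1_s, 0)
  expect_lt(pd$t1_s, pd$t2_s)
  expect_lte(pd$buffered_fraction, 1)
  expect_gt(pd$buffered_fraction, 0.5)
  sh <- tidy(pd)
  expect_setequal(unique(sh$compartment),
                  c("extracellular", "neuron", "astrocyte"))
  # the astrocyte share at t2 is the buffered fraction, by construction
  astro <- sh[sh$compartment == "astrocyte", ]
  at_t2 <- astro$frac_of_release[which.min(abs(astro$time_s - pd$t2_s))]
  expect_equal(at_t2, pd$buffered_fraction, tolerance = 1e-6)
  # an unstimulated run has no release to decompose
  expect_error(phase_decomposition(run_simulation(protocol("rest"), test_cal)),
               "no neuronal potassium release")
})

test_that("net uptake is zero at rest and normalised to the reference maximum", {
  d <- uptake_phase_diagram(single = test_single)
  pre <- d[d$protocol == "single", ]
  expect_lt(abs(pre$uptake[1]), 1e-12)        # resting point (2.5, 0)
  expect_equal(max(d$uptake_norm), 1)
  expect_gt(d$K_o[which.max(d$uptake)], 2.5)  # uptake grows with the transient
})

test_that("firing probability matches constructed and Poisson ensembles", {
  # every pulse fires: probability 1 in every bin
  freq <- 5
  spikes <- tidyr::expand_grid(run = 1:10, time = seq(1100, 5900, by = 200))
  fp <- firing_probability(spikes, stim_freq = freq, n_runs = 10,
                           window_s = c(1, 6))
  expect_true(all(fp$probability == 1))

  # Poisson spiking at rate lambda: estimate approx lambda / freq
  set.seed(7)
  lambda <- 2
  n_runs <- 60
  sp <- purrr::map(1:n_runs, function(r) {
    k <- rpois(5, lambda)  # 5 one-second bins
    tibble::tibble(run = r,
                   time = 1000 * (rep(1:5, k) + runif(sum(k))))
  })
  fp2 <- firing_probability(dplyr::bind_rows(sp), stim_freq = freq,
                            n_runs = n_runs, window_s = c(1, 6))
  se <- sqrt(lambda / freq * (1 - lambda / freq) / n_runs)
  expect_true(all(abs(fp2$probability - lambda / freq) < 4 * se))

  expect_error(firing_probability(spikes, stim_freq = freq, n_runs = 0,
                                  window_s = c(1, 6)), "empty")
})
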