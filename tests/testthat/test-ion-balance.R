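test_that("pump flux: resting value, saturation, monotonicity, domain", {
  expect_equal(pump_flux(2.5, 12, 1), (1 + 7.3 / 2.5)^-2 * (12 / 22)^3)
  expect_equal(pump_flux(2.5, 12, 1), 0.0105609, tolerance = 1e-5)
  expect_equal(pump_flux(1e9, 1e9, 0.3), 0.3, tolerance = 1e-6)
  k <- seq(1, 20, by = 0.5)
  expect_true(all(diff(pump_flux(k, 12, 1)) > 0))
  expect_true(all(diff(pump_flux(2.5, k, 1)) > 0))
  expect_error(pump_flux(0, 12, 1), "positive")
  expect_error(pump_flux(2.5, -3, 1), "positive")
})

test_that("current-to-flux conversion is linear through zero", {
  expect_equal(current_to_flux(0, 1e-6), 0)
  expect_equal(current_to_flux(c(1, 2, -4), 5e-7), c(5e-7, 1e-6, -2e-6))
})

test_that("volume-weighted K+ and Na+ derivatives cancel algebraically", {
  ex <- test_cal$params$exchange
  set.seed(33)
  for (rep in 1:20) {
    ions <- c(K_o = runif(1, 1, 12), Na_n = runif(1, 5, 30),
              Na_a = runif(1, 5, 30))
    i_K <- rnorm(1, 0, 1e-3)
    i_Kir <- rnorm(1, 0, 1e-3)
    i_Na <- rnorm(1, 0, 1e-3)
    dk <- potassium_derivatives(ions, i_K, i_Kir, ex)
    expect_equal(dk[["dK_o"]] + dk[["dK_n"]] / ex$vol_ratio_N +
                   dk[["dK_a"]] / ex$vol_ratio_A, 0, tolerance = 1e-15)
    dk_off <- potassium_derivatives(ions, i_K, i_Kir, ex, kir_enabled = FALSE)
    expect_equal(dk_off[["dK_o"]] + dk_off[["dK_n"]] / ex$vol_ratio_N +
                   dk_off[["dK_a"]] / ex$vol_ratio_A, 0, tolerance = 1e-15)
    dna <- sodium_derivatives(ions, i_Na, ex)
    expect_equal(dna[["dNa_o"]] + dna[["dNa_n"]] / ex$vol_ratio_N +
                   dna[["dNa_a"]] / ex$vol_ratio_A, 0, tolerance = 1e-15)
  }
})

test_that("all ion derivatives vanish at the calibrated resting preset", {
  d <- model_derivatives(test_cal$y0, I_app = 0, calibration = test_cal)
  expect_lt(max(abs(d)), 1e-12)
  # Kir-blocked mode: the compensation flux keeps the same rest stationary
  d_off <- model_derivatives(test_cal$y0, I_app = 0, calibration = test_cal,
                             kir_enabled = FALSE)
  expect_lt(max(abs(d_off)), 1e-12)
})

test_that("conservation holds along simulated trajectories in both Kir modes", {
  for (tr in list(test_single,
                  run_simulation(protocol("single", kir = FALSE,
                                          horizon_s = 8), test_cal))) {
    drift_k <- abs(total_k(tr) - total_k(tr)[1]) / total_k(tr)[1]
    drift_na <- abs(total_na(tr) - total_na(tr)[1]) / total_na(tr)[1]
    seconds <- max(tr$time) / 1000
    expect_lt(max(drift_k) / seconds, 1e-6)
    expect_lt(max(drift_na) / seconds, 1e-6)
    expect_true(all(tr[c("K_o", "K_n", "K_a", "Na_o", "Na_n", "Na_a")] > 0))
  }
})

test_that("the R derivative field reproduces the compiled integrator", {
  # short reference integration: R-side RK4 on model_derivatives vs the core
  pr <- protocol("single", horizon_s = 0.2, onset_ms = 50, record_ms = 0.1)
  core <- run_simulation(pr, test_cal)

  p <- test_cal$params
  y <- test_cal$y0
  dt <- 0.1
  scale <- p$synapse_scale
  rk4 <- function(y) {
    f <- function(yy) model_derivatives(yy, I_app = scale * p$synapse$A_se * yy[["e"]],
                                        calibration = test_cal)
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n_steps <- 2000
  ref <- matrix(NA_real_, n_steps + 1, length(y))
  ref[1, ] <- y
  for (s in 1:n_steps) {
    if (s == 501) {  # impulse at 50 ms, jump-then-flow
      jump <- p$synapse$U_se * y[["r"]]
      y[["r"]] <- y[["r"]] - jump
      y[["e"]] <- y[["e"]] + jump
    }
    y <- rk4(y)
    ref[s + 1, ] <- y
  }
  expect_equal(ref[, 3], core$V_N, tolerance = 1e-10)
  expect_equal(ref[, 8], core$K_o, tolerance = 1e-12)
})

test_that("a general-purpose stiff solver agrees with the fixed-step core", {
  skip_if_not_installed("deSolve")
  # autonomous stretch (no impulses): start from a perturbed state
  y0 <- test_cal$y0
  y0[["V_N"]] <- -66  # subthreshold perturbation: smooth relaxation stretch
  y0[["K_o"]] <- 3.2
  p <- test_cal$params
  f_desolve <- function(t, y, parms) {
    yy <- setNames(y, names(test_cal$y0))
    list(unname(model_derivatives(yy, I_app = 0, calibration = test_cal)))
  }
  sol <- deSolve::ode(unname(y0), times = c(0, 500), func = f_desolve,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  core <- kirdyn:::core_run(test_cal$pv, y0, 500, record_ms = 500)
  end_core <- core[nrow(core), 2:14]
  end_ode <- sol[2, -1]
  expect_equal(unname(end_core), unname(end_ode), tolerance = 1e-6)
})
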