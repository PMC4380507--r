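ap <- model_parameters()$astrocyte

test_that("Kir current vanishes exactly at V_KA + V_A1 and is outward at rest", {
  v0 <- nernst_potential(2.5, 135) + ap$V_A1
  expect_equal(kir_current(v0, 2.5, 135, ap), 0)
  expect_gt(kir_current(-80, 2.5, 135, ap), 0)  # outward at rest
  expect_error(kir_current(-80, -1, 135, ap), "positive")
})

test_that("Kir current scales with the square root of extracellular K+", {
  # quadruple both concentrations: V_KA unchanged, sqrt factor doubles
  i1 <- kir_current(-80, 2.5, 135, ap)
  i4 <- kir_current(-80, 10, 540, ap)
  expect_equal(i4 / i1, 2, tolerance = 1e-12)
  # and via the explicit Nernst override at fixed V_KA
  vka <- nernst_potential(2.5, 135)
  expect_equal(kir_current(-80, 10, 135, ap, v_ka = vka) /
                 kir_current(-80, 2.5, 135, ap, v_ka = vka), 2)
})

test_that("the I-V reversal moves toward depolarised values as K+ rises", {
  rev_at <- function(k) {
    iv <- kir_iv_curve(seq(-120, 0, by = 0.5), K_o = k, K_a = 135, params = ap)
    kirdyn:::cross_up(iv$V, iv$I, 0)
  }
  expect_lt(rev_at(2.5), rev_at(5))
  expect_lt(rev_at(5), rev_at(10))
  # with K_o = K_a the Nernst term is zero and the reversal sits at V_A1
  iv <- kir_iv_curve(seq(-40, 40, by = 0.1), K_o = 135, K_a = 135, params = ap)
  expect_equal(kirdyn:::cross_up(iv$V, iv$I, 0), ap$V_A1, tolerance = 0.1)
  # monotone increasing where the Boltzmann factor varies slowly
  iv2 <- kir_iv_curve(seq(-120, -75, by = 1), K_o = 2.5, K_a = 135, params = ap)
  expect_true(all(diff(iv2$I) > 0))
})

test_that("the astrocyte is stationary at the calibrated rest", {
  asp <- test_cal$params$astrocyte
  st <- c(V_A = -80)
  for (k in 1:100) st <- step_astrocyte(st, 2.5, 135, asp, dt = 0.1)
  expect_lt(abs(st[["V_A"]] + 80), 1e-9)
})

test_that("closed-form relaxation time: value, scaling, simulated check", {
  # independent evaluation of the formula, assembled from its pieces
  rtf <- 8.314 * 308 / 96485 * 1000
  v_ka <- rtf * log(2.5 / 135)
  expected <- 15 * (1 + exp((-80 - v_ka - 34) / 19.23)) /
    (0.06 * sqrt(2.5)) / 1000
  expect_equal(tau_kir_relaxation(), expected)
  expect_equal(expected, 0.2617, tolerance = 1e-3)
  # 1/sqrt(K_o) scaling at fixed Nernst potential
  expect_equal(tau_kir_relaxation(K_o = 10, K_a = 540) / tau_kir_relaxation(),
               0.5, tolerance = 1e-12)

  # relax the isolated astrocyte membrane (fixed ions, no leak) and compare
  ap0 <- ap
  ap0$g_lA <- 0
  ap0$V_lA <- 0
  st <- c(V_A = -79.5)
  times <- seq(0, 400, by = 1)
  v <- numeric(length(times))
  v[1] <- st[["V_A"]]
  for (k in 2:length(times)) {
    for (j in 1:10) st <- step_astrocyte(st, 2.5, 135, ap0, dt = 0.1, scale = 1)
    v[k] <- st[["V_A"]]
  }
  v_inf <- nernst_potential(2.5, 135) + ap$V_A1
  fit <- lm(log(v - v_inf) ~ times)
  tau_sim <- -1 / coef(fit)[[2]] / 1000
  expect_lt(abs(tau_sim / tau_kir_relaxation() - 1), 0.35)
})

test_that("I-V fitting recovers the generating constants", {
  vka <- nernst_potential(3, 145)
  d <- kir_iv_curve(seq(-100, 20, by = 2), K_o = 3, K_a = 145, params = ap)
  fit <- fit_kir_iv(d, K_o = 3, K_a = 145)
  expect_equal(fit$V_A1, ap$V_A1, tolerance = 0.05)
  expect_equal(fit$V_A2, ap$V_A2, tolerance = 0.5)
  expect_equal(fit$V_A3, ap$V_A3, tolerance = 0.5)
  expect_equal(fit$G, ap$G_kir, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)

  # samples all on one side of the reversal cannot be fitted
  oneside <- d[d$I > 0, ]
  expect_error(fit_kir_iv(oneside, K_o = 3, K_a = 145), "reversal")

  # misreading the recording K+ by 0.5 mM barely moves the fitted curve
  fit2 <- fit_kir_iv(d, K_o = 3.5, K_a = 145)
  pred1 <- kir_current(d$V, 3, 145, list(G_kir = fit$G, V_A1 = fit$V_A1,
                                         V_A2 = fit$V_A2, V_A3 = fit$V_A3,
                                         kir_scale = 1))
  pred2 <- kir_current(d$V, 3.5, 145, list(G_kir = fit2$G, V_A1 = fit2$V_A1,
                                           V_A2 = fit2$V_A2, V_A3 = fit2$V_A3,
                                           kir_scale = 1))
  expect_lt(max(abs(pred2 - pred1)) / max(abs(d$I)), 0.1)
})
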