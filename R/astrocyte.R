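#' Kir4.1 channel current
#'
#' Inward-rectifier current
#' `I_Kir = G (V_A - V_KA - V_A1) sqrt(K_o) / (1 + exp((V_A - V_KA - V_A2)/V_A3))`
#' with `V_KA` the astrocytic K+ Nernst potential. The current is zero exactly
#' at `V_A = V_KA + V_A1`, scales with the square root of extracellular K+ and
#' is gated by a Boltzmann open-fraction that closes the channel on
#' depolarisation (inward rectification). Outward current is positive.
#'
#' @param V_A astrocytic membrane potential (mV); vectorised.
#' @param K_o,K_a extracellular / astrocytic K+ (mM), positive.
#' @param params the `astrocyte` component of [model_parameters()].
#' @param v_ka optional override of the Nernst potential (mV); defaults to
#'   `nernst_potential(K_o, K_a)`.
#' @param scale whole-cell conductance scale applied to `G_kir`; defaults to
#'   the calibrated `params$kir_scale` when present, else 1.
#' @param temperature temperature (K).
#' @return Current in pA (with `G_kir` in nS and potentials in mV).
#' @export
#' @examples
#' ap <- model_parameters()$astrocyte
#' kir_current(nernst_potential(2.5, 135) + ap$V_A1, 2.5, 135, ap) # exactly 0
kir_current <- function(V_A, K_o, K_a, params, v_ka = NULL, scale = NULL,
                        temperature = 308) {
  if (any(K_o <= 0) || any(K_a <= 0)) abort("concentrations must be positive")
  v_ka <- v_ka %||% nernst_potential(K_o, K_a, temperature)
  scale <- scale %||% params$kir_scale %||% 1
  if (is.na(scale)) scale <- 1
  g <- params$G_kir * scale
  g * (V_A - v_ka - params$V_A1) * sqrt(K_o) /
    (1 + exp((V_A - v_ka - params$V_A2) / params$V_A3))
}

#' Kir4.1 current-voltage relation
#'
#' Pointwise evaluation of [kir_current()] over a voltage range, as used to
#' characterise the channel at different extracellular-to-astrocytic K+
#' ratios.
#'
#' @param V voltages to evaluate (mV).
#' @inheritParams kir_current
#' @return Tibble with columns `V`, `I`, `K_o`.
#' @export
kir_iv_curve <- function(V = seq(-120, 20, by = 1), K_o = 2.5, K_a = 135,
                         params = model_parameters()$astrocyte, scale = 1) {
  out <- lapply(K_o, function(k) {
    tibble(V = V, I = kir_current(V, k, K_a, params, scale = scale), K_o = k)
  })
  bind_rows(out)
}

#' Advance the astrocyte membrane potential by one step
#'
#' One Runge-Kutta step of `C_A dV_A/dt = -(I_Kir + I_lA)` at fixed ion
#' concentrations.
#'
#' @param state named vector/list with `V_A` (mV).
#' @inheritParams kir_current
#' @param dt time step (ms).
#' @return Named vector `c(V_A = ...)`.
#' @export
step_astrocyte <- function(state, K_o, K_a, params, dt, scale = NULL) {
  stopifnot(dt > 0)
  f <- function(v) {
    -(kir_current(v, K_o, K_a, params, scale = scale) +
        params$g_lA * (v - params$V_lA)) / params$C_A
  }
  v <- state[["V_A"]]
  k1 <- f(v); k2 <- f(v + dt / 2 * k1); k3 <- f(v + dt / 2 * k2); k4 <- f(v + dt * k3)
  c(V_A = v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' Closed-form Kir-mediated relaxation time of the astrocyte potential
#'
#' `tau_A = C_A (1 + exp((V_A - V_KA - V_A2)/V_A3)) / (G_kir sqrt(K_o))`,
#' the approximate membrane time constant obtained by linearising the Kir
#' current around `V_A` and neglecting the leak and the voltage dependence of
#' the Boltzmann factor. Evaluated with the nominal (single-channel scale)
#' conductance unless `scale` says otherwise. Scales as `1/sqrt(K_o)`.
#'
#' @param params a [model_parameters()] bundle (astrocyte constants are
#'   taken from it).
#' @param K_o,K_a extracellular / astrocytic K+ (mM).
#' @param V_A membrane potential at which to linearise (mV).
#' @param scale conductance scale; default 1 (nominal constants).
#' @return Time constant in seconds.
#' @export
#' @examples
#' tau_kir_relaxation() # nominal constants at rest
tau_kir_relaxation <- function(params = model_parameters(), K_o = 2.5,
                               K_a = 135, V_A = -80, scale = 1) {
  stopifnot(K_o > 0)
  ap <- params$astrocyte
  v_ka <- nernst_potential(K_o, K_a, params$physics$temperature)
  boltz <- 1 + exp((V_A - v_ka - ap$V_A2) / ap$V_A3)
  # pF / nS = ms
  ap$C_A * boltz / (ap$G_kir * scale * sqrt(K_o)) / 1000
}

#' Fit the Kir4.1 I-V parameters from current-voltage samples
#'
#' Recovers the three potential constants of the Kir model from sampled
#' (V, I) pairs at known concentrations: `V_A1` from the zero-current
#' potential (linear interpolation across the sign change), then `V_A2`,
#' `V_A3` and the conductance amplitude by Levenberg-Marquardt least squares
#' on the full expression.
#'
#' @param data data frame with columns `V` (mV) and `I`.
#' @param K_o,K_a concentrations at which the samples were recorded (mM).
#' @param temperature temperature (K).
#' @return List of class `kir_iv_fit` with `V_A1`, `V_A2`, `V_A3`, `G`,
#'   `r_squared` and the underlying `nls` fit.
#' @export
fit_kir_iv <- function(data, K_o = 3, K_a = 145, temperature = 308) {
  stopifnot(all(c("V", "I") %in% names(data)), nrow(data) >= 3)
  data <- data[order(data$V), ]
  v_ka <- nernst_potential(K_o, K_a, temperature)
  sgn <- sign(data$I)
  flip <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  if (length(flip) == 0 && !any(sgn == 0)) {
    abort("samples do not span the reversal potential (no sign change in I)")
  }
  if (any(sgn == 0)) {
    v0 <- data$V[which(sgn == 0)[1]]
  } else {
    i <- flip[1]
    v0 <- data$V[i] - data$I[i] * (data$V[i + 1] - data$V[i]) /
      (data$I[i + 1] - data$I[i])
  }
  V_A1 <- v0 - v_ka
  fit <- minpack.lm::nlsLM(
    I ~ G * (V - v_ka - V_A1) * sqrt(K_o) / (1 + exp((V - v_ka - VA2) / VA3)),
    data = data,
    start = list(G = 0.06, VA2 = 30, VA3 = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((data$I - mean(data$I))^2)
  structure(list(
    V_A1 = V_A1,
    V_A2 = coef(fit)[["VA2"]],
    V_A3 = coef(fit)[["VA3"]],
    G = coef(fit)[["G"]],
    r_squared = 1 - ss_res / ss_tot,
    fit = fit,
    K_o = K_o, K_a = K_a
  ), class = "kir_iv_fit")
}

#' @export
print.kir_iv_fit <- function(x, ...) {
  cat(sprintf("<kir_iv_fit> V_A1 = %.2f mV, V_A2 = %.2f mV, V_A3 = %.2f mV, G = %.4f nS (R^2 = %.4f)\n",
              x$V_A1, x$V_A2, x$V_A3, x$G, x$r_squared))
  invisible(x)
}
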