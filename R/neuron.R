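#' Hodgkin-Huxley rate constants
#'
#' Opening/closing rates of the n, m and h gates as functions of the membrane
#' displacement `v = V_rest - V_N` (original Hodgkin-Huxley voltage
#' convention: `v = 0` at rest, hyperpolarisation positive). The removable
#' singularities of `alpha_n` at `v = -10` and `alpha_m` at `v = -25` are
#' replaced by their analytic limits.
#'
#' @param v membrane displacement (mV), may be a vector.
#' @return A tibble with columns `v`, `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h` (ms^-1).
#' @export
#' @examples
#' hh_rate_constants(-10)$alpha_n # 0.1 (limit value)
hh_rate_constants <- function(v) {
  stopifnot(all(is.finite(v)))
  ratio <- function(x) ifelse(abs(x) < 1e-7, 10, x / expm1(0.1 * x))
  tibble(
    v = v,
    alpha_n = 0.01 * ratio(v + 10),
    beta_n  = 0.125 * exp(v / 80),
    alpha_m = 0.1 * ratio(v + 25),
    beta_m  = 4 * exp(v / 18),
    alpha_h = 0.07 * exp(v / 20),
    beta_h  = 1 / (exp(0.1 * (v + 30)) + 1)
  )
}

# steady-state gating at a given displacement
hh_gates_inf <- function(v = 0) {
  rc <- hh_rate_constants(v)
  c(n = rc$alpha_n / (rc$alpha_n + rc$beta_n),
    m = rc$alpha_m / (rc$alpha_m + rc$beta_m),
    h = rc$alpha_h / (rc$alpha_h + rc$beta_h))
}

#' Nernst equilibrium potential
#'
#' `(RT/F) ln(c_out / c_in)` for a monovalent cation, in millivolts.
#'
#' @param c_out,c_in outside / inside concentrations (mM), positive.
#' @param temperature temperature (K).
#' @return Potential in mV.
#' @export
#' @examples
#' nernst_potential(2.5, 135) # about -105.9 mV at 308 K
nernst_potential <- function(c_out, c_in, temperature = 308) {
  if (any(c_out <= 0) || any(c_in <= 0)) {
    abort("concentrations must be strictly positive")
  }
  8.314 * temperature / 96485 * 1000 * log(c_out / c_in)
}

#' Neuronal membrane currents
#'
#' Sodium, potassium and leak currents (outward positive) at the given state
#' and ion concentrations, with Nernst reversal potentials computed from the
#' instantaneous concentrations.
#'
#' @param state named vector/list with `V_N`, `n`, `m`, `h`.
#' @param ions named vector with `K_o`, `K_n`, `Na_o`, `Na_n` (mM).
#' @param params the `neuron` component of [model_parameters()] (with `V_lN`
#'   filled, e.g. after [calibrate_model()]).
#' @param temperature temperature (K) for the Nernst terms.
#' @return Named vector `c(I_Na, I_K, I_lN)` in pA.
#' @export
neuron_currents <- function(state, ions, params, temperature = 308) {
  g_Na <- params$g_Na * (params$density_scale %||% 1)
  g_K <- params$g_K * (params$density_scale %||% 1)
  E_Na <- nernst_potential(ions[["Na_o"]], ions[["Na_n"]], temperature)
  E_K <- nernst_potential(ions[["K_o"]], ions[["K_n"]], temperature)
  V <- state[["V_N"]]
  c(I_Na = g_Na * state[["m"]]^3 * state[["h"]] * (V - E_Na),
    I_K  = g_K * state[["n"]]^4 * (V - E_K),
    I_lN = params$g_lN * (V - params$V_lN))
}

#' Advance the neuron by one time step
#'
#' One fourth-order Runge-Kutta step of the membrane equation
#' `C_N dV/dt = -(I_Na + I_K + I_lN) + I_app` together with the three gating
#' equations, at fixed ion concentrations, plus an optional additive
#' stochastic voltage increment (Euler-Maruyama splitting).
#'
#' @inheritParams neuron_currents
#' @param I_app applied current (pA), held constant across the step.
#' @param dt time step (ms).
#' @param noise_increment additive voltage increment (mV) applied after the
#'   deterministic update.
#' @return Updated named state vector `c(V_N, n, m, h)`.
#' @export
step_neuron <- function(state, I_app, ions, params, dt, noise_increment = 0,
                        temperature = 308) {
  stopifnot(dt > 0)
  g_Na <- params$g_Na * (params$density_scale %||% 1)
  g_K <- params$g_K * (params$density_scale %||% 1)
  E_Na <- nernst_potential(ions[["Na_o"]], ions[["Na_n"]], temperature)
  E_K <- nernst_potential(ions[["K_o"]], ions[["K_n"]], temperature)
  f <- function(y) {
    rc <- hh_rate_constants(params$V_rest - y[1])
    I_Na <- g_Na * y[3]^3 * y[4] * (y[1] - E_Na)
    I_K <- g_K * y[2]^4 * (y[1] - E_K)
    I_lN <- params$g_lN * (y[1] - params$V_lN)
    c((-(I_Na + I_K + I_lN) + I_app) / params$C_N,
      rc$alpha_n * (1 - y[2]) - rc$beta_n * y[2],
      rc$alpha_m * (1 - y[3]) - rc$beta_m * y[3],
      rc$alpha_h * (1 - y[4]) - rc$beta_h * y[4])
  }
  y <- c(state[["V_N"]], state[["n"]], state[["m"]], state[["h"]])
  k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  y[1] <- y[1] + noise_increment
  c(V_N = y[1], n = y[2], m = y[3], h = y[4])
}

#' Detect action potentials in a voltage trace
#'
#' Upward threshold crossings with a refractory lockout. Deterministic given
#' the trace; robust for full-height action potentials.
#'
#' @param x a simulation trace (from [run_simulation()]) or a numeric voltage
#'   vector.
#' @param time sample times (ms); taken from the trace when `x` is one.
#' @param threshold crossing threshold (mV).
#' @param refractory minimum spacing between detected spikes (ms).
#' @return Numeric vector of spike times (ms); empty if none.
#' @export
detect_spikes <- function(x, time = NULL, threshold = -20, refractory = 2) {
  if (inherits(x, "kir_trace")) {
    time <- x$time
    x <- x$V_N
  }
  if (length(x) == 0) return(numeric(0))
  if (is.null(time)) time <- seq_along(x)
  up <- which(diff(x >= threshold) == 1) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- time[up]
  keep <- c(TRUE, diff(times) > refractory)
  # enforce lockout sequentially (diff-based pass is enough for monotone times)
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] > refractory) out <- c(out, t)
  out
}
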