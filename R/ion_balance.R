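#' Na/K pump flux
#'
#' Saturating pump flux `i_max (1 + 7.3/K_o)^-2 (1 + 10/Na_in)^-3`, strictly
#' increasing in both extracellular K+ and intracellular Na+. The same form
#' is used for the neuronal and astrocytic pumps; each pump cycle moves 2 K+
#' in and 3 Na+ out (the stoichiometric factors are applied by the flux
#' balance equations, not here).
#'
#' @param K_o extracellular K+ (mM), positive; vectorised.
#' @param Na_in intracellular Na+ (mM), positive; vectorised.
#' @param i_max maximal pump rate (mM ms^-1).
#' @return Pump flux in mM ms^-1.
#' @export
#' @examples
#' pump_flux(2.5, 12, 1) # about 0.01056
pump_flux <- function(K_o, Na_in, i_max) {
  if (any(K_o <= 0) || any(Na_in <= 0)) abort("concentrations must be positive")
  i_max * (1 + 7.3 / K_o)^-2 * (1 + 10 / Na_in)^-3
}

#' Convert a membrane current to a concentration flux
#'
#' Linear conversion `I * gamma`, where `gamma` corresponds to
#' `1 / (q N_A Vol)` for the compartment volume the current discharges into.
#' Absolute volumes are never specified, so `gamma` is a calibrated constant
#' (see [calibrate_model()]).
#'
#' @param I current (pA); vectorised.
#' @param gamma conversion factor (mM ms^-1 pA^-1), positive.
#' @return Flux in mM ms^-1.
#' @export
current_to_flux <- function(I, gamma) {
  stopifnot(gamma > 0)
  I * gamma
}

#' Potassium mass-balance derivatives
#'
#' Volume-weighted conservation equations for the three K+ pools:
#' \deqn{dK_o/dt = i_K - 2 i_{pump,N} - 2 i_{pump,A} + i_{Kir}}
#' \deqn{dK_n/dt = (-i_K + 2 i_{pump,N}) Vol_o/Vol_N}
#' \deqn{dK_a/dt = (-i_{Kir} + 2 i_{pump,A}) Vol_o/Vol_A}
#' With Kir blocked (`kir_enabled = FALSE`) the `i_Kir` slot is replaced in
#' both equations by the constant compensation flux solved at rest, so that
#' the resting state remains stationary; the volume-weighted total is then
#' still conserved exactly.
#'
#' @param ions named vector with `K_o`, `Na_n`, `Na_a` (mM).
#' @param i_K neuronal K+ efflux (mM ms^-1, extracellular units).
#' @param i_Kir astrocytic Kir flux (mM ms^-1, positive = into the
#'   extracellular space); ignored when `kir_enabled = FALSE`.
#' @param ex the `exchange` component of a calibrated [model_parameters()].
#' @param kir_enabled logical.
#' @return Named vector `c(dK_o, dK_n, dK_a)` in mM ms^-1.
#' @export
potassium_derivatives <- function(ions, i_K, i_Kir, ex, kir_enabled = TRUE) {
  ip_N <- pump_flux(ions[["K_o"]], ions[["Na_n"]], ex$i_maxN)
  ip_A <- pump_flux(ions[["K_o"]], ions[["Na_a"]], ex$i_maxA)
  if (!kir_enabled) i_Kir <- ex$comp_flux
  c(dK_o = i_K - 2 * ip_N - 2 * ip_A + i_Kir,
    dK_n = (-i_K + 2 * ip_N) * ex$vol_ratio_N,
    dK_a = (-i_Kir + 2 * ip_A) * ex$vol_ratio_A)
}

#' Sodium mass-balance derivatives
#'
#' \deqn{dNa_o/dt = i_{Na} + i_{NalN} + 3 i_{pump,N} + 3 i_{pump,A} + i_{NalA}}
#' \deqn{dNa_n/dt = (-i_{Na} - 3 i_{pump,N} - i_{NalN}) Vol_o/Vol_N}
#' \deqn{dNa_a/dt = (-i_{NalA} - 3 i_{pump,A}) Vol_o/Vol_A}
#' The 3:2 pump stoichiometry appears as the factor 3 here and 2 in
#' [potassium_derivatives()]; `i_NalN`, `i_NalA` are the constant sodium leak
#' rates (negative: leak into the cells) solved at rest.
#'
#' @inheritParams potassium_derivatives
#' @param i_Na neuronal Na+ flux (mM ms^-1, extracellular units; negative for
#'   inward current).
#' @return Named vector `c(dNa_o, dNa_n, dNa_a)` in mM ms^-1.
#' @export
sodium_derivatives <- function(ions, i_Na, ex) {
  ip_N <- pump_flux(ions[["K_o"]], ions[["Na_n"]], ex$i_maxN)
  ip_A <- pump_flux(ions[["K_o"]], ions[["Na_a"]], ex$i_maxA)
  c(dNa_o = i_Na + ex$i_NalN + 3 * ip_N + 3 * ip_A + ex$i_NalA,
    dNa_n = (-i_Na - 3 * ip_N - ex$i_NalN) * ex$vol_ratio_N,
    dNa_a = (-ex$i_NalA - 3 * ip_A) * ex$vol_ratio_A)
}

#' Full model derivative field (reference implementation)
#'
#' Time derivatives of the complete 13-dimensional state, written in plain R.
#' This duplicates the compiled integrator's right-hand side and exists as an
#' inspectable reference (the test suite checks the two against each other
#' and against a general-purpose ODE solver).
#'
#' @param state named numeric vector with elements `r`, `e`, `V_N`, `n`, `m`,
#'   `h`, `V_A`, `K_o`, `K_n`, `K_a`, `Na_o`, `Na_n`, `Na_a`.
#' @param I_app applied current (pA). If `NULL`, computed from the synaptic
#'   state as `synapse_scale * A_se * e`.
#' @param calibration a [calibrate_model()] result (or any object with a
#'   filled `params` bundle).
#' @param kir_enabled logical; Kir-blocked mode otherwise.
#' @return Named vector of derivatives (per ms).
#' @export
model_derivatives <- function(state, I_app = NULL, calibration = NULL,
                              kir_enabled = TRUE) {
  calibration <- calibration %||% calibrate_model()
  p <- calibration$params
  if (is.null(I_app)) I_app <- p$synapse_scale * p$synapse$A_se * state[["e"]]

  ds <- c(r = (1 - state[["r"]] - state[["e"]]) / p$synapse$tau_rec,
          e = -state[["e"]] / p$synapse$tau_inac)

  rc <- hh_rate_constants(p$neuron$V_rest - state[["V_N"]])
  cur <- neuron_currents(state, state, p$neuron, p$physics$temperature)
  dn <- c(V_N = (-(sum(cur)) + I_app) / p$neuron$C_N,
          n = rc$alpha_n * (1 - state[["n"]]) - rc$beta_n * state[["n"]],
          m = rc$alpha_m * (1 - state[["m"]]) - rc$beta_m * state[["m"]],
          h = rc$alpha_h * (1 - state[["h"]]) - rc$beta_h * state[["h"]])

  if (kir_enabled) {
    I_Kir <- kir_current(state[["V_A"]], state[["K_o"]], state[["K_a"]],
                         p$astrocyte, temperature = p$physics$temperature)
    dVA <- -(I_Kir + p$astrocyte$g_lA * (state[["V_A"]] - p$astrocyte$V_lA)) /
      p$astrocyte$C_A
  } else {
    I_Kir <- 0
    dVA <- 0
  }

  i_K <- current_to_flux(cur[["I_K"]], p$exchange$gamma_N)
  i_Na <- current_to_flux(cur[["I_Na"]], p$exchange$gamma_N)
  i_Kir <- current_to_flux(I_Kir, p$exchange$gamma_A)
  dk <- potassium_derivatives(state, i_K, i_Kir, p$exchange, kir_enabled)
  dna <- sodium_derivatives(state, i_Na, p$exchange)
  c(ds, dn, V_A = unname(dVA),
    setNames(dk, c("K_o", "K_n", "K_a")),
    setNames(dna, c("Na_o", "Na_n", "Na_a")))
}
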