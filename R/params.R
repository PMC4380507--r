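#' Synaptic facilitation-depression parameters
#'
#' Time constants and strength of the three-state (recovered / effective /
#' inactive) synaptic resource model that generates the applied current
#' `I_app = A_se * e`. Two named presets are available: `"control"`
#' (tau_rec 300 ms, tau_inac 200 ms, A_se 7) and `"kir_ko"` (500 ms, 160 ms,
#' A_se 10), the latter refitted for the Kir4.1-blocked condition.
#'
#' @param preset `"control"` or `"kir_ko"`.
#' @return A list with elements `tau_rec` (ms), `tau_inac` (ms), `A_se`
#'   (dimensionless synaptic strength), `U_se` (utilisation fraction) and
#'   `preset`.
#' @export
#' @examples
#' synaptic_params("control")
synaptic_params <- function(preset = c("control", "kir_ko")) {
  preset <- match.arg(preset)
  out <- switch(preset,
    control = list(tau_rec = 300, tau_inac = 200, A_se = 7, U_se = 0.8),
    kir_ko  = list(tau_rec = 500, tau_inac = 160, A_se = 10, U_se = 0.8)
  )
  out$preset <- preset
  structure(out, class = "kir_synaptic_params")
}

#' Full model parameter bundle
#'
#' Assembles the nominal parameters of the tri-compartment model: synaptic
#' drive, neuronal membrane, astrocytic membrane, ion-exchange machinery,
#' resting concentrations and physical constants. Entries set to `NA` (leak
#' reversal potentials, pump maxima, sodium leak rates, the two
#' current-to-flux conversion factors, the Kir conductance scale and the
#' synaptic current scale) are solved or fitted by [calibrate_model()]; all
#' other values are fixed model constants.
#'
#' The neuronal channel conductances are expressed as a channel density:
#' `g_Na`/`g_K` are per-unit values (15 and 4 nS) multiplied by
#' `density_scale` at assembly time. With the per-unit values alone the
#' membrane time scale (C_N = 136 pF) is orders of magnitude slower than the
#' gating kinetics and the cell cannot spike; `density_scale = 100` restores
#' action-potential dynamics while preserving the printed 15:4 Na:K ratio.
#'
#' @param preset synaptic preset passed to [synaptic_params()].
#' @return A list of class `kir_params` with components `synapse`, `neuron`,
#'   `astrocyte`, `exchange`, `ions` and `physics`.
#' @export
#' @examples
#' p <- model_parameters()
#' p$astrocyte$V_A1
model_parameters <- function(preset = c("control", "kir_ko")) {
  preset <- match.arg(preset)
  physics <- list(R = 8.314, temperature = 308, faraday = 96485)
  physics$RT_over_F <- physics$R * physics$temperature / physics$faraday * 1000 # mV
  structure(list(
    synapse = synaptic_params(preset),
    neuron = list(
      g_Na = 15, g_K = 4,            # nS per density unit
      density_scale = 100,           # channel-density (membrane area) scale
      g_lN = 0.07,                   # nS
      V_lN = NA_real_,               # mV, solved at rest
      V_rest = -70,                  # mV (resting calibration target)
      C_N = 136,                     # pF
      spike_threshold = -20,         # mV, for spike detection
      refractory = 2                 # ms
    ),
    astrocyte = list(
      G_kir = 0.06,                  # nS (single-channel scale, 60 pS)
      kir_scale = NA_real_,          # whole-cell scale, fitted
      V_A1 = 14.83,                  # mV; zero-current offset of the Kir I-V
      V_A2 = 34,                     # mV; Boltzmann half-activation offset
      V_A3 = 19.23,                  # mV; Boltzmann slope
      C_A = 15,                      # pF
      g_lA = 0.1,                    # nS
      V_lA = NA_real_,               # mV, solved at rest
      V_rest = -80                   # mV
    ),
    exchange = list(
      gamma_N = NA_real_,            # mM ms^-1 pA^-1, fitted
      gamma_A = NA_real_,            # mM ms^-1 pA^-1, fitted
      i_maxN = NA_real_,             # mM ms^-1, solved at rest
      i_maxA = NA_real_,             # mM ms^-1, solved at rest
      vol_ratio_N = 0.5,             # extracellular / neuronal volume
      vol_ratio_A = 0.5,             # extracellular / astrocytic volume
      i_NalN = NA_real_,             # mM ms^-1, solved at rest
      i_NalA = NA_real_,             # mM ms^-1, solved at rest
      comp_flux = NA_real_           # mM ms^-1, Kir-blocked compensation
    ),
    ions = c(K_o = 2.5, K_n = 135, K_a = 135,
             Na_o = 116, Na_n = 12, Na_a = 12),  # resting preset, mM
    synapse_scale = NA_real_,        # pA per unit of A_se * e, fitted
    noise = list(sigma = 0.68,       # pA^2 ms^-1 (nominal label)
                 gain = NA_real_,    # calibrated to the 1 mV fluctuation band
                 target_sd = 0.25),  # mV; 1 mV peak-to-peak ~ +/- 2 SD
    physics = physics
  ), class = "kir_params")
}

#' @export
print.kir_params <- function(x, ...) {
  cat("<kir_params> tri-compartment model parameters\n")
  cat("  synaptic preset:", x$synapse$preset,
      sprintf("(tau_rec %g ms, tau_inac %g ms, A_se %g, U_se %g)\n",
              x$synapse$tau_rec, x$synapse$tau_inac, x$synapse$A_se, x$synapse$U_se))
  cat(sprintf("  neuron: g_Na %g nS, g_K %g nS (density x%g), C_N %g pF, rest %g mV\n",
              x$neuron$g_Na, x$neuron$g_K, x$neuron$density_scale,
              x$neuron$C_N, x$neuron$V_rest))
  cat(sprintf("  astrocyte: G_kir %g nS, V_A1/2/3 %g/%g/%g mV, C_A %g pF, rest %g mV\n",
              x$astrocyte$G_kir, x$astrocyte$V_A1, x$astrocyte$V_A2,
              x$astrocyte$V_A3, x$astrocyte$C_A, x$astrocyte$V_rest))
  cat("  resting ions (mM):",
      paste(names(x$ions), x$ions, sep = "=", collapse = ", "), "\n")
  ncal <- sum(is.na(c(x$neuron$V_lN, x$astrocyte$V_lA, x$astrocyte$kir_scale,
                      unlist(x$exchange), x$synapse_scale, x$noise$gain)))
  if (ncal > 0) {
    cat("  ", ncal, "quantities pending calibration (see calibrate_model())\n")
  } else {
    cat("  fully calibrated\n")
  }
  invisible(x)
}

#' @export
print.kir_synaptic_params <- function(x, ...) {
  cat(sprintf("<kir_synaptic_params> %s: tau_rec %g ms, tau_inac %g ms, A_se %g, U_se %g\n",
              x$preset, x$tau_rec, x$tau_inac, x$A_se, x$U_se))
  invisible(x)
}
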