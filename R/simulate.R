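#' Define a stimulation protocol
#'
#' Bundles everything one run needs: the stimulation kind and its timing, the
#' Kir mode, the synaptic preset, noise and integration settings.
#'
#' Kinds: `"single"` (one impulse), `"tetanic"` (default 100 Hz for 1 s),
#' `"repetitive"` (default 10 Hz for 30 s), `"subfiring"` (square current
#' pulses of `pulse_width` ms at `freq_hz`, amplitude calibrated just below
#' the deterministic firing threshold, membrane noise on) and `"rest"` (no
#' input). When `kir = FALSE` the Kir current and astrocytic leak are clamped
#' to zero, a constant compensation flux holds resting extracellular K+, and
#' the synaptic preset defaults to `"kir_ko"` (the protocol requires the
#' refitted synaptic parameters in that condition).
#'
#' @param kind protocol label.
#' @param freq_hz stimulation frequency (Hz); per-kind default.
#' @param duration_s stimulation duration (s); per-kind default.
#' @param onset_ms time of the first impulse/pulse (ms); the pre-onset
#'   segment provides the analysis baseline.
#' @param horizon_s total simulated time (s); per-kind default.
#' @param kir logical, astrocytic Kir4.1 conductance enabled.
#' @param preset synaptic preset; defaults to `"control"` (`"kir_ko"` when
#'   `kir = FALSE`).
#' @param noise_sigma white-noise intensity label (pA^2 ms^-1); default 0
#'   except for `"subfiring"` (0.68).
#' @param seed RNG seed used when noise is on.
#' @param dt integration step (ms).
#' @param record_ms sampling interval of the returned trace (ms).
#' @param pulse_amp_pA square-pulse amplitude for `"subfiring"`; `NULL` means
#'   calibrate via [calibrate_subfiring()].
#' @param pulse_width_ms square-pulse width (ms).
#' @return A `kir_protocol` list.
#' @export
#' @examples
#' protocol("tetanic")
protocol <- function(kind = c("single", "tetanic", "repetitive", "subfiring", "rest"),
                     freq_hz = NULL, duration_s = NULL, onset_ms = 1000,
                     horizon_s = NULL, kir = TRUE, preset = NULL,
                     noise_sigma = NULL, seed = NULL, dt = 0.1,
                     record_ms = 1, pulse_amp_pA = NULL, pulse_width_ms = 5) {
  kind <- match.arg(kind)
  freq_hz <- freq_hz %||% switch(kind, tetanic = 100, repetitive = 10,
                                 subfiring = 5, 0)
  duration_s <- duration_s %||% switch(kind, tetanic = 1, repetitive = 30,
                                       subfiring = 15, 0)
  horizon_s <- horizon_s %||% switch(kind,
    single = 16, tetanic = 41, repetitive = 61, subfiring = duration_s + 1,
    rest = 10)
  noise_sigma <- noise_sigma %||% if (kind == "subfiring") 0.68 else 0
  preset <- preset %||% if (kir) "control" else "kir_ko"
  if (!kir && preset != "kir_ko") {
    warn("Kir-blocked runs normally use the 'kir_ko' synaptic preset")
  }
  stopifnot(dt > 0, horizon_s > 0)
  structure(list(kind = kind, freq_hz = freq_hz, duration_s = duration_s,
                 onset_ms = onset_ms, horizon_s = horizon_s, kir = kir,
                 preset = preset, noise_sigma = noise_sigma, seed = seed,
                 dt = dt, record_ms = record_ms,
                 pulse_amp_pA = pulse_amp_pA, pulse_width_ms = pulse_width_ms),
            class = "kir_protocol")
}

#' @export
print.kir_protocol <- function(x, ...) {
  cat(sprintf("<kir_protocol> %s | %g Hz x %g s from t = %g ms | horizon %g s | Kir %s | preset %s",
              x$kind, x$freq_hz, x$duration_s, x$onset_ms, x$horizon_s,
              if (x$kir) "on" else "off", x$preset))
  if (x$noise_sigma > 0) cat(sprintf(" | noise sigma %g, seed %s",
                                     x$noise_sigma, x$seed %||% "unset"))
  cat("\n")
  invisible(x)
}

#' Run one simulation of the coupled model
#'
#' Integrates the full 13-state system with fixed-step RK4 (default
#' dt = 0.1 ms) under the given protocol. Deterministic when
#' `noise_sigma = 0`; otherwise reproducible given `seed`.
#'
#' @param protocol a [protocol()].
#' @param calibration a [calibrate_model()] result; computed (and cached) for
#'   the default parameters when `NULL`.
#' @return A tibble of class `kir_trace`, one row per recorded sample:
#'   `time` (ms), synaptic fractions `r`, `e`, neuronal `V_N` (mV) and gates
#'   `n`, `m`, `h`, astrocytic `V_A` (mV), concentrations `K_o`, `K_n`,
#'   `K_a`, `Na_o`, `Na_n`, `Na_a` (mM), `I_app` and `I_Kir` (pA) and the
#'   astroglial net K+ `uptake` flux (mM ms^-1, extracellular units).
#'   The protocol and flat parameter vector travel as attributes.
#' @export
#' @examples
#' \donttest{
#' cal <- calibrate_model()
#' tr <- run_simulation(protocol("single"), cal)
#' max(tr$K_o) - 2.5
#' }
run_simulation <- function(protocol, calibration = NULL) {
  stopifnot(inherits(protocol, "kir_protocol"))
  calibration <- calibration %||% calibrate_model()

  params <- calibration$params
  pv <- calibration$pv
  if (protocol$preset != params$synapse$preset) {
    sp <- synaptic_params(protocol$preset)
    pv[c("tau_rec", "tau_inac", "A_se", "U_se")] <-
      c(sp$tau_rec, sp$tau_inac, sp$A_se, sp$U_se)
  }
  pv[["kir_on"]] <- as.numeric(protocol$kir)

  impulses <- numeric(0)
  pulses <- numeric(0)
  pulse_amp <- 0
  if (protocol$kind %in% c("single", "tetanic", "repetitive")) {
    impulses <- make_impulse_train(protocol$kind, t0 = protocol$onset_ms,
                                   freq_hz = protocol$freq_hz,
                                   duration_s = protocol$duration_s)$times
  } else if (protocol$kind == "subfiring") {
    pulse_amp <- protocol$pulse_amp_pA %||%
      calibrate_subfiring(calibration, freq_hz = protocol$freq_hz)$amplitude
    pulses <- seq(protocol$onset_ms,
                  protocol$onset_ms + protocol$duration_s * 1000 - 1,
                  by = 1000 / protocol$freq_hz)
  }

  if (protocol$noise_sigma > 0 && !is.null(protocol$seed)) {
    set.seed(protocol$seed)
  }
  m <- core_run(pv, calibration$y0, protocol$horizon_s * 1000,
                dt = protocol$dt, impulse_times = impulses,
                pulse_amp = pulse_amp, pulse_width = protocol$pulse_width_ms,
                pulse_times = pulses, noise_sigma = protocol$noise_sigma,
                noise_gain = params$noise$gain %||% 1,
                record_ms = protocol$record_ms)
  out <- as_tibble(as.data.frame(m))
  class(out) <- c("kir_trace", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "pv") <- pv
  attr(out, "pulse_amp") <- pulse_amp
  out
}

#' Run a seeded ensemble of stochastic simulations
#'
#' Repeats `run_simulation()` with seeds `base_seed + 0:(n_runs-1)` and
#' collects spike times per run (and, optionally, thinned traces of selected
#' channels). Two ensembles with the same base seed are identical.
#'
#' @param protocol a [protocol()] with `noise_sigma > 0` (typically
#'   `"subfiring"`).
#' @param n_runs number of independent runs.
#' @param base_seed first seed.
#' @param calibration a [calibrate_model()] result.
#' @param keep_traces keep per-run traces of `channels` (memory permitting).
#' @param channels trace columns retained when `keep_traces = TRUE`.
#' @param trace_record_ms sampling interval for retained traces (ms).
#' @return A `kir_ensemble`: list with `spikes` (tibble `run`, `time`),
#'   `n_runs`, `protocol` and optionally `traces` (list of tibbles).
#' @export
run_ensemble <- function(protocol, n_runs = 100, base_seed = 1,
                         calibration = NULL, keep_traces = FALSE,
                         channels = c("V_N", "K_o"), trace_record_ms = 10) {
  stopifnot(n_runs >= 1)
  if (protocol$noise_sigma <= 0) {
    abort("ensembles are for stochastic protocols (noise_sigma > 0)")
  }
  calibration <- calibration %||% calibrate_model()
  # resolve the pulse amplitude once so every run shares it
  if (protocol$kind == "subfiring" && is.null(protocol$pulse_amp_pA)) {
    protocol$pulse_amp_pA <-
      calibrate_subfiring(calibration, freq_hz = protocol$freq_hz)$amplitude
  }
  thr <- calibration$params$neuron$spike_threshold
  refr <- calibration$params$neuron$refractory
  spikes <- vector("list", n_runs)
  traces <- if (keep_traces) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    pr <- protocol
    pr$seed <- base_seed + i - 1
    pr$record_ms <- if (keep_traces) protocol$record_ms else 0.5
    tr <- run_simulation(pr, calibration)
    st <- detect_spikes(tr$V_N, tr$time, threshold = thr, refractory = refr)
    spikes[[i]] <- tibble(run = i, time = st)
    if (keep_traces) {
      keep <- unique(c("time", channels))
      idx <- seq(1, nrow(tr), by = max(1, round(trace_record_ms / pr$record_ms)))
      traces[[i]] <- tr[idx, keep]
    }
  }
  structure(list(spikes = bind_rows(spikes), n_runs = n_runs,
                 protocol = protocol, base_seed = base_seed, traces = traces),
            class = "kir_ensemble")
}

#' @export
print.kir_ensemble <- function(x, ...) {
  cat(sprintf("<kir_ensemble> %d runs of '%s' (%g Hz, Kir %s), %d spikes total\n",
              x$n_runs, x$protocol$kind, x$protocol$freq_hz,
              if (x$protocol$kir) "on" else "off", nrow(x$spikes)))
  invisible(x)
}
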