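#' Transient kinetics of a trace channel
#'
#' Quantifies a stimulus-evoked transient the way evoked responses are
#' measured on chart records: amplitudes relative to the mean over the
#' `baseline_ms` window preceding stimulus onset, rise time between the 20%
#' and 80% crossings of the peak amplitude on the rising limb, decay time
#' between the 80% and 20% crossings on the falling limb (linear
#' interpolation between samples), plus a single-exponential fit of the
#' falling limb giving `tau` and its R-squared.
#'
#' @param trace a `kir_trace` from [run_simulation()], or a data frame with a
#'   `time` column (ms).
#' @param channel column to analyse (e.g. `"V_A"`, `"K_o"`).
#' @param onset_ms stimulus onset; taken from the trace's protocol when
#'   available.
#' @param baseline_ms length of the pre-onset baseline window (ms).
#' @param fit_tau also fit the exponential decay (see [fit_decay()]).
#' @return One-row tibble: `channel`, `baseline`, `peak_amplitude`,
#'   `t_peak_ms`, `rise_ms`, `decay_ms`, `tau_ms`, `r_squared`.
#' @export
kinetics <- function(trace, channel = "V_A", onset_ms = NULL,
                     baseline_ms = 500, fit_tau = TRUE) {
  onset_ms <- onset_ms %||% attr(trace, "protocol")$onset_ms %||%
    abort("supply onset_ms (trace carries no protocol)")
  k <- transient_kinetics(trace$time, trace[[channel]], onset_ms, baseline_ms)
  tau <- r2 <- NA_real_
  if (fit_tau) {
    fit <- tryCatch(
      fit_decay(trace, channel = channel,
                window = c(onset_ms + k$t_peak, max(trace$time))),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      tau <- fit$tau_ms
      r2 <- fit$r_squared
    }
  }
  tibble(channel = channel, baseline = k$baseline,
         peak_amplitude = k$peak_amplitude, t_peak_ms = k$t_peak,
         rise_ms = k$rise, decay_ms = k$decay, tau_ms = tau, r_squared = r2)
}

#' Single-exponential decay fit
#'
#' Least-squares fit of `y(t) = y0 + A exp(-(t - t_start)/tau)` over a time
#' window on the falling limb of a transient, via Levenberg-Marquardt.
#' Fits with R-squared below 0.97 are flagged (`quality_ok = FALSE` in
#' [generics::glance()]).
#'
#' @param trace trace or data frame with `time` (ms).
#' @param channel column to fit.
#' @param window `c(start, end)` in ms; must lie on a decaying stretch.
#' @return `kir_decay_fit` object with `tau_ms`, `r_squared`, `baseline`,
#'   `amplitude` and the underlying `nls` fit.
#' @export
#' @examples
#' d <- data.frame(time = 0:5000)
#' d$y <- 2 * exp(-d$time / 2000)
#' fit_decay(d, "y", c(0, 5000))$tau_ms # 2000
fit_decay <- function(trace, channel, window) {
  stopifnot(length(window) == 2)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 5) abort("decay window contains fewer than 5 samples")
  t <- trace$time[sel] - trace$time[sel][1]
  y <- trace[[channel]][sel]
  if (y[1] <= y[length(y)]) abort("window is not decaying")

  # log-linear starting values against the terminal level
  y_end <- min(y) - 0.05 * abs(diff(range(y)))
  lf <- lm(log(y - y_end) ~ t)
  start <- list(y0 = unname(y_end), A = unname(exp(coef(lf)[1])),
                tau = unname(-1 / coef(lf)[2]))
  if (!is.finite(start$tau) || start$tau <= 0) start$tau <- diff(range(t)) / 3
  fit <- minpack.lm::nlsLM(y ~ y0 + A * exp(-t / tau),
                           data = data.frame(t = t, y = y),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(tau_ms = coef(fit)[["tau"]],
                 r_squared = 1 - ss_res / ss_tot,
                 baseline = coef(fit)[["y0"]],
                 amplitude = coef(fit)[["A"]],
                 channel = channel, window = window, fit = fit, n = sum(sel)),
            class = "kir_decay_fit")
}

#' @export
print.kir_decay_fit <- function(x, ...) {
  cat(sprintf("<kir_decay_fit> %s: tau = %.1f ms (%.3g s), R^2 = %.4f%s\n",
              x$channel, x$tau_ms, x$tau_ms / 1000, x$r_squared,
              if (x$r_squared < 0.97) "  [below the 0.97 quality bar]" else ""))
  invisible(x)
}

#' Three-phase decomposition of the potassium cycle
#'
#' Splits a stimulation run into the canonical phases of the neuroglial K+
#' cycle: phase 0 (neuronal release, onset to `t1`, where `t1` is the last
#' time the net neuronal K+ efflux exceeds a small threshold), phase 1
#' (astroglial uptake, `t1` to `t2`, where `t2` is the time of the
#' astrocytic K+ content peak) and phase 2 (slow redistribution back to the
#' neuron). The buffered fraction is the astrocyte's volume-weighted K+ gain
#' at `t2` divided by the cumulative (volume-weighted) neuronal release up to
#' `t1`. Per-compartment K+ changes are also returned as time courses,
#' normalised either to baseline extracellular K+ or to the total release.
#'
#' @param trace a `kir_trace` from a stimulation run.
#' @param flux_threshold efflux threshold defining the end of release
#'   (mM ms^-1).
#' @return `kir_phase_decomposition` with `t1_s`, `t2_s`,
#'   `buffered_fraction`, `total_release_mM` and a long `shares` tibble
#'   (`time_s`, `compartment`, `delta_mM` in extracellular-equivalent units,
#'   `frac_of_baseline`, `frac_of_release`).
#' @export
phase_decomposition <- function(trace, flux_threshold = 1e-6) {
  pv <- attr(trace, "pv") %||% abort("trace carries no parameter vector")
  onset <- attr(trace, "protocol")$onset_ms
  eff <- neuronal_k_efflux(trace, pv)
  on <- trace$time >= onset
  if (!any(on & eff > flux_threshold)) {
    abort("no neuronal potassium release detected after onset")
  }
  dtm <- trace$time[2] - trace$time[1]
  t1 <- max(trace$time[on & eff > flux_threshold]) - onset
  release <- cumsum(ifelse(on & eff > 0, eff, 0)) * dtm
  total_release <- release[max(which(trace$time <= onset + t1))]

  vr_N <- pv[["vr_N"]]
  vr_A <- pv[["vr_A"]]
  k_a0 <- trace$K_a[1]
  i2 <- which.max(trace$K_a)
  t2 <- trace$time[i2] - onset
  buffered <- (trace$K_a[i2] - k_a0) / vr_A / total_release

  deltas <- tibble(
    time_s = rep((trace$time - onset) / 1000, 3),
    compartment = rep(c("extracellular", "neuron", "astrocyte"),
                      each = nrow(trace)),
    delta_mM = c(trace$K_o - trace$K_o[1],
                 (trace$K_n - trace$K_n[1]) / vr_N,
                 (trace$K_a - k_a0) / vr_A)
  )
  deltas$frac_of_baseline <- c(
    (trace$K_o - trace$K_o[1]) / trace$K_o[1],
    (trace$K_n - trace$K_n[1]) / trace$K_n[1],
    (trace$K_a - k_a0) / k_a0
  )
  deltas$frac_of_release <- deltas$delta_mM / total_release

  structure(list(t1_s = t1 / 1000, t2_s = t2 / 1000,
                 buffered_fraction = buffered,
                 total_release_mM = total_release,
                 shares = deltas),
            class = "kir_phase_decomposition")
}

#' @export
print.kir_phase_decomposition <- function(x, ...) {
  cat(sprintf("<kir_phase_decomposition> t1 = %.2f s, t2 = %.2f s, released %.2f mM (ECS units), %.1f%% buffered by the astrocyte at t2\n",
              x$t1_s, x$t2_s, x$total_release_mM, 100 * x$buffered_fraction))
  invisible(x)
}

#' Astroglial net-uptake phase diagram
#'
#' Parametric curve of the astroglial net K+ uptake flux against the
#' instantaneous extracellular K+ concentration, for one or more protocols.
#' Uptake is normalised to its maximum over the trace named `"repetitive"`
#' (if present), otherwise to the global maximum.
#'
#' @param ... named `kir_trace` objects (e.g. `single = tr1, tetanic = tr2,
#'   repetitive = tr3`).
#' @param normalize optional explicit normalisation constant (mM ms^-1).
#' @return Tibble with `protocol`, `K_o` (mM), `uptake` (mM ms^-1) and
#'   `uptake_norm`.
#' @export
uptake_phase_diagram <- function(..., normalize = NULL) {
  traces <- list(...)
  if (length(traces) == 1 && is.null(names(traces))) names(traces) <- "trace"
  stopifnot(length(traces) >= 1, !is.null(names(traces)))
  long <- bind_rows(lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    tibble(protocol = nm, time = tr$time, K_o = tr$K_o, uptake = tr$uptake)
  }))
  ref <- normalize %||%
    if ("repetitive" %in% names(traces)) {
      max(traces[["repetitive"]]$uptake)
    } else {
      max(long$uptake)
    }
  long$uptake_norm <- long$uptake / ref
  long$time <- NULL
  long
}

#' Time-resolved firing probability over an ensemble
#'
#' For each time bin, the mean over runs of (spike count in the bin) divided
#' by the number of stimulation pulses per bin, clipped to `[0, 1]` (bursts
#' can yield more spikes than pulses).
#'
#' @param ensemble a [run_ensemble()] result, or a tibble with columns `run`
#'   and `time` (ms).
#' @param stim_freq stimulation frequency (Hz); taken from the ensemble's
#'   protocol when available.
#' @param bin_s bin width (s).
#' @param n_runs,window_s required when passing a bare spike table: number of
#'   runs and the time window `c(start, end)` in seconds.
#' @return Tibble of class `kir_firing_curve`: `bin_start_s`, `probability`,
#'   `n_runs`.
#' @export
firing_probability <- function(ensemble, stim_freq = NULL, bin_s = 1,
                               n_runs = NULL, window_s = NULL) {
  if (inherits(ensemble, "kir_ensemble")) {
    spikes <- ensemble$spikes
    stim_freq <- stim_freq %||% ensemble$protocol$freq_hz
    n_runs <- ensemble$n_runs
    window_s <- c(ensemble$protocol$onset_ms / 1000,
                  ensemble$protocol$onset_ms / 1000 +
                    ensemble$protocol$duration_s)
  } else {
    spikes <- ensemble
    if (is.null(stim_freq) || is.null(n_runs) || is.null(window_s)) {
      abort("bare spike tables need stim_freq, n_runs and window_s")
    }
  }
  if (n_runs < 1) abort("empty ensemble")
  breaks <- seq(window_s[1], window_s[2], by = bin_s)
  if (length(breaks) < 2) abort("window shorter than one bin")
  starts <- breaks[-length(breaks)]
  per_bin <- vapply(seq_along(starts), function(b) {
    lo <- starts[b] * 1000
    hi <- (starts[b] + bin_s) * 1000
    counts <- tabulate(spikes$run[spikes$time >= lo & spikes$time < hi],
                       nbins = n_runs)
    mean(pmin(counts / (stim_freq * bin_s), 1))
  }, numeric(1))
  out <- tibble(bin_start_s = starts - window_s[1], probability = per_bin,
                n_runs = n_runs)
  class(out) <- c("kir_firing_curve", class(out))
  attr(out, "stim_freq") <- stim_freq
  out
}
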