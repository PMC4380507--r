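# internal interpolation / crossing helpers shared by analysis and calibration

# first time vv rises through lev (linear interpolation), NA if never
cross_up <- function(tt, vv, lev) {
  idx <- which(diff(vv >= lev) == 1)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  tt[i] + (lev - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
}

# first time vv falls through lev (linear interpolation), NA if never
cross_down <- function(tt, vv, lev) {
  idx <- which(diff(vv <= lev) == 1)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  tt[i] + (lev - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
}

# 20-80% kinetics of a single transient, relative to a pre-onset baseline
transient_kinetics <- function(time, value, onset, baseline_window = 500) {
  pre <- time < onset & time >= onset - baseline_window
  if (!any(pre)) abort("trace does not include a pre-stimulus baseline window")
  baseline <- mean(value[pre])
  x <- value - baseline
  pk <- which.max(abs(x))
  amp <- x[pk]
  if (abs(amp) < 10 * (sd(x[pre]) + 1e-12)) {
    abort("no clear transient above baseline noise")
  }
  xs <- x / amp  # normalised, peak = 1
  rise <- cross_up(time[1:pk], xs[1:pk], 0.8) - cross_up(time[1:pk], xs[1:pk], 0.2)
  post <- pk:length(xs)
  decay <- cross_down(time[post], xs[post], 0.2) - cross_down(time[post], xs[post], 0.8)
  list(baseline = baseline, peak_amplitude = amp, t_peak = time[pk] - onset,
       rise = rise, decay = decay)
}

# net neuronal K+ efflux into the extracellular space (mM/ms, ECS units),
# reconstructed from a recorded trace and the parameter vector it carries
neuronal_k_efflux <- function(trace, pv) {
  E_K <- pv[["RTF"]] * log(trace$K_o / trace$K_n)
  i_K <- pv[["gamma_N"]] * pv[["g_K"]] * trace$n^4 * (trace$V_N - E_K)
  ip_N <- pv[["i_maxN"]] *
    (1 + 7.3 / trace$K_o)^-2 * (1 + 10 / trace$Na_n)^-3
  i_K - 2 * ip_N
}
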