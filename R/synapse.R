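#' Build a stimulation impulse train
#'
#' Impulse times for the facilitation-depression synapse. A `"single"`
#' stimulation is one impulse at `t0`; `"tetanic"` is 100 Hz for 1 s (100
#' impulses, 10 ms apart); `"repetitive"` is 10 Hz for 30 s (300 impulses,
#' 100 ms apart). Frequencies and durations other than the named defaults are
#' allowed for train kinds.
#'
#' @param kind one of `"single"`, `"tetanic"`, `"repetitive"`.
#' @param t0 time of the first impulse (ms).
#' @param freq_hz impulse frequency (Hz); defaults to 100 for tetanic and 10
#'   for repetitive.
#' @param duration_s train duration (s); defaults to 1 for tetanic and 30 for
#'   repetitive.
#' @return An object of class `kir_impulse_train`: list with `times` (ms,
#'   strictly increasing) and `kind`.
#' @export
#' @examples
#' make_impulse_train("single")
#' length(make_impulse_train("tetanic")$times) # 100
make_impulse_train <- function(kind = c("single", "tetanic", "repetitive"),
                               t0 = 0, freq_hz = NULL, duration_s = NULL) {
  if (!is.character(kind) || !kind[1] %in% c("single", "tetanic", "repetitive")) {
    abort(paste0("unknown stimulation kind: ", kind[1]))
  }
  kind <- kind[1]
  if (kind == "single") {
    times <- t0
  } else {
    freq_hz <- freq_hz %||% switch(kind, tetanic = 100, repetitive = 10)
    duration_s <- duration_s %||% switch(kind, tetanic = 1, repetitive = 30)
    stopifnot(freq_hz > 0, duration_s > 0)
    n <- round(freq_hz * duration_s)
    times <- t0 + (seq_len(n) - 1) * 1000 / freq_hz
  }
  structure(list(times = times, kind = kind), class = "kir_impulse_train")
}

#' @export
print.kir_impulse_train <- function(x, ...) {
  cat(sprintf("<kir_impulse_train> %s: %d impulse(s), t = %g..%g ms\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Advance the synaptic resource state by one time step
#'
#' Integrates the continuous part of the three-state resource model
#' (`dr/dt = i / tau_rec`, `de/dt = -e / tau_inac`, `i = 1 - r - e`) with a
#' single fourth-order Runge-Kutta step. When `impulse = TRUE` the
#' instantaneous jump `r -> r - U_se r`, `e -> e + U_se r` is applied before
#' the continuous step (jump-then-flow), matching the instantaneous
#' activation of a fraction `U_se` of recovered resources.
#'
#' @param state list or named vector with `r` and `e` (the inactive fraction
#'   is `1 - r - e`).
#' @param params a [synaptic_params()] list.
#' @param dt time step (ms).
#' @param impulse logical; apply the stimulation jump at the start of the
#'   step.
#' @return Named vector with components `r`, `e`, `i`.
#' @export
step_synapse <- function(state, params, dt, impulse = FALSE) {
  stopifnot(dt > 0)
  r <- state[["r"]]; e <- state[["e"]]
  if (isTRUE(impulse)) {
    jump <- params$U_se * r
    r <- r - jump
    e <- e + jump
  }
  f <- function(y) c((1 - y[1] - y[2]) / params$tau_rec, -y[2] / params$tau_inac)
  y <- c(r, e)
  k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  c(r = y[1], e = y[2], i = 1 - y[1] - y[2])
}

#' Applied synaptic current
#'
#' `I_app = A_se * e`, the current injected into the neuron in proportion to
#' the effective fraction of synaptic resources. The optional `scale` maps
#' the dimensionless `A_se * e` onto picoamperes; the calibrated value lives
#' in `calibrate_model()$params$synapse_scale`.
#'
#' @param state synaptic state with element `e`.
#' @param params a [synaptic_params()] list.
#' @param scale current scale (pA per unit), default 1.
#' @return Applied current (same scale as `scale`).
#' @export
#' @examples
#' synaptic_current(c(r = 0.2, e = 0.8), synaptic_params()) # 5.6
synaptic_current <- function(state, params, scale = 1) {
  scale * params$A_se * state[["e"]]
}
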