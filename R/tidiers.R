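#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.kir_calibration <- function(x, ...) x$anchors

#' @export
glance.kir_calibration <- function(x, ...) {
  tibble(gamma_N = x$knobs[["gamma_N"]], gamma_A = x$knobs[["gamma_A"]],
         kir_scale = x$knobs[["kir_scale"]],
         synapse_scale = x$knobs[["synapse_scale"]],
         rest_residual = x$rest_residual,
         max_anchor_error = max(abs(x$anchors$rel_error)),
         converged = max(abs(x$anchors$rel_error)) < 0.10)
}

#' @export
tidy.kir_decay_fit <- function(x, ...) {
  est <- coef(x$fit)
  tibble(term = names(est), estimate = unname(est))
}

#' @export
glance.kir_decay_fit <- function(x, ...) {
  tibble(tau_ms = x$tau_ms, tau_s = x$tau_ms / 1000,
         r_squared = x$r_squared, quality_ok = x$r_squared >= 0.97, n = x$n)
}

#' @export
tidy.kir_iv_fit <- function(x, ...) {
  tibble(term = c("V_A1", "V_A2", "V_A3", "G"),
         estimate = c(x$V_A1, x$V_A2, x$V_A3, x$G))
}

#' @export
glance.kir_iv_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, K_o = x$K_o, K_a = x$K_a)
}

#' @export
tidy.kir_phase_decomposition <- function(x, ...) x$shares

#' @export
glance.kir_phase_decomposition <- function(x, ...) {
  tibble(t1_s = x$t1_s, t2_s = x$t2_s,
         buffered_fraction = x$buffered_fraction,
         total_release_mM = x$total_release_mM)
}
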