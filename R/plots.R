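#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs vars
#' @export
ggplot2::autoplot

#' Plot selected channels of a simulation trace
#'
#' @param object a `kir_trace`.
#' @param channels trace columns to show.
#' @param time_unit `"s"` or `"ms"`.
#' @param ... unused.
#' @return A ggplot, one facet per channel (free y scales).
#' @export
autoplot.kir_trace <- function(object, channels = c("V_N", "V_A", "K_o", "I_app"),
                               time_unit = c("s", "ms"), ...) {
  time_unit <- match.arg(time_unit)
  div <- if (time_unit == "s") 1000 else 1
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), dplyr::all_of(c("time", channels))),
    -"time", names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = channels)
  ggplot(long, aes(x = .data$time / div, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$channel), scales = "free_y", ncol = 1) +
    labs(x = paste0("time (", time_unit, ")"), y = NULL)
}

#' Plot a time-resolved firing-probability curve
#'
#' @param object a [firing_probability()] result.
#' @param ... unused.
#' @export
autoplot.kir_firing_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_start_s + 0.5, y = .data$probability)) +
    geom_line() +
    geom_point() +
    labs(x = "time (s)", y = "firing probability",
         title = sprintf("%g Hz sub-firing stimulation (n = %d runs)",
                         attr(object, "stim_freq") %||% NA, object$n_runs[1]))
}

#' Plot Kir4.1 I-V curves at several extracellular K+ levels
#'
#' @param K_o extracellular K+ concentrations (mM), one curve each.
#' @param K_a astrocytic K+ (mM).
#' @param V voltage range (mV).
#' @param params astrocyte parameter list.
#' @param scale conductance scale (default 1 = nominal constants).
#' @return A ggplot of current against voltage.
#' @export
plot_kir_iv <- function(K_o = c(2.5, 5, 10), K_a = 135,
                        V = seq(-120, 20, by = 1),
                        params = model_parameters()$astrocyte, scale = 1) {
  d <- kir_iv_curve(V, K_o, K_a, params, scale = scale)
  d$K_o <- factor(d$K_o)
  ggplot(d, aes(x = .data$V, y = .data$I, colour = .data$K_o)) +
    geom_line() +
    labs(x = "membrane potential (mV)", y = "Kir4.1 current (pA)",
         colour = "[K+]o (mM)")
}

#' @importFrom rlang .data
NULL
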