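#' Plot an absorption spectrum with pulse markers
#'
#' @param spectrum tibble from [absorption_spectrum()].
#' @param pulse_energies_ev optional vector of pulse central energies to mark.
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum, pulse_energies_ev = NULL) {
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(x = .data$energy_ev, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation energy (eV)",
                  y = "intensity (arb. u.)") +
    ggplot2::theme_minimal()
  if (!is.null(pulse_energies_ev))
    p <- p + ggplot2::geom_vline(xintercept = pulse_energies_ev,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' Scatter plot of selected excitation energies and start times
#'
#' The time--energy distribution of the accepted initial conditions; for short
#' resonant pulses this shows the characteristic teardrop shape with a late,
#' on-resonance tail.
#'
#' @param selection tibble from [eoe_select()].
#' @param ensemble the `population_ensemble` the selection was computed from
#'   (provides per-geometry excitation energies).
#' @return a ggplot object.
#' @export
plot_selection <- function(selection, ensemble) {
  acc <- selection$accepted
  df <- tibble::tibble(t_start_fs = selection$t_start_fs[acc],
                       energy_ev = hartree_to_ev(ensemble$energy_gap[acc]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start_fs, y = .data$energy_ev)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "start time (fs)", y = "excitation energy (eV)") +
    ggplot2::theme_minimal()
}

#' Plot time-shifted ensemble observables
#'
#' @param observables tibble from [shifted_observables()] (or the
#'   `$observables` of a `qd_trajectory`, using its S1 columns).
#' @param reference optional tibble with columns `time_fs`, `mean_R_S1`,
#'   `sd_R_S1` drawn as dashed reference curves (e.g. quantum dynamics).
#' @return a ggplot object.
#' @export
plot_observables <- function(observables, reference = NULL) {
  p <- ggplot2::ggplot(observables,
                       ggplot2::aes(x = .data$time_fs, y = .data$mean_R_S1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_R_S1 - .data$sd_R_S1,
                                      ymax = .data$mean_R_S1 + .data$sd_R_S1),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "<R> (bohr)") +
    ggplot2::theme_minimal()
  if (!is.null(reference))
    p <- p + ggplot2::geom_line(data = reference, linetype = "dashed") +
      ggplot2::geom_line(
        data = reference,
        ggplot2::aes(y = .data$mean_R_S1 + .data$sd_R_S1), linetype = "dotted") +
      ggplot2::geom_line(
        data = reference,
        ggplot2::aes(y = .data$mean_R_S1 - .data$sd_R_S1), linetype = "dotted")
  p
}

#' @importFrom rlang .data
NULL
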