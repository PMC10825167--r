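#' Plot condition-averaged pupil traces
#'
#' Mean trace per condition with a +/- 1 SEM ribbon, coloured by variable
#' luminance, the standard diagnostic view of a tagging session.
#'
#' @param averages Output of [average_trials()].
#' @param window Optional [analysis_window()] drawn as dashed verticals.
#' @return A ggplot.
#' @export
plot_traces <- function(averages, window = NULL) {
  p <- ggplot2::ggplot(
    averages,
    ggplot2::aes(.data$time_s, .data$mean,
                 colour = .data$condition, fill = .data$condition,
                 group = .data$condition)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "variable\n(cd/m²)") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "pupil diameter (baseline-corrected)") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_vline(xintercept = c(window$t1, window$t2),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot amplitude spectra per condition
#'
#' @param spectra A tibble of [spectrum()] outputs row-bound with a
#'   `condition` column, or a single spectrum.
#' @param tag_frequency_hz Optional tagging frequency, drawn as a dotted
#'   vertical line.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectra, tag_frequency_hz = NULL) {
  aes <- if ("condition" %in% names(spectra)) {
    ggplot2::aes(.data$freq, .data$amplitude,
                 colour = .data$condition, group = .data$condition)
  } else {
    ggplot2::aes(.data$freq, .data$amplitude)
  }
  p <- ggplot2::ggplot(spectra, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "single-sided amplitude") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(spectra)) {
    p <- p + ggplot2::scale_colour_viridis_c(name = "variable\n(cd/m²)")
  }
  if (!is.null(tag_frequency_hz)) {
    p <- p + ggplot2::geom_vline(xintercept = tag_frequency_hz,
                                 linetype = "dotted")
  }
  p
}

#' Amplitude-tuning and phase plot of an analysis
#'
#' Normalised tagging-frequency amplitude against variable luminance with
#' the fitted spline and its minimum, plus the (rescaled) phase curve whose
#' inversion confirms the minimum.
#'
#' @param x A `pftm_analysis` (from [pftm_analyze()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pftm_analysis <- function(x, ...) {
  res <- normalise_amplitudes(x$results)
  est <- x$estimate
  mx <- max(x$results$tag_amplitude)
  curve <- dplyr::mutate(est$fit$curve, amplitude = .data$amplitude / mx)
  ph <- dplyr::mutate(res, phase01 = (unwrap_degrees(.data$tag_phase_deg) -
                                        est$phase_transition$plateau_lo) /
                        max(est$phase_transition$excursion, 1))
  ggplot2::ggplot(res, ggplot2::aes(.data$condition, .data$norm_amplitude)) +
    ggplot2::geom_point(colour = "darkred") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$level, .data$amplitude),
                       colour = "darkred", linetype = "dashed") +
    ggplot2::geom_line(data = ph, ggplot2::aes(y = .data$phase01),
                       colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = est$min_luminance,
                        colour = "darkred", linetype = "dotted") +
    ggplot2::geom_vline(xintercept = x$config$fixed_luminance,
                        colour = "grey40", linetype = "dotted") +
    ggplot2::labs(
      x = "variable luminance (cd/m²)",
      y = "normalised tag amplitude (red) / scaled phase (green)",
      title = sprintf("equiluminance estimate: %.3g cd/m² (ratio %.3f)",
                      est$min_luminance, est$ratio)
    ) +
    ggplot2::theme_minimal()
}

#' Psychometric-function plot of a Quick fit
#'
#' Observed proportions (point size ~ trials) with the fitted Quick curve
#' and the 50% point of subjective equality.
#'
#' @param x A `pftm_quick_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pftm_quick_fit <- function(x, ...) {
  d <- dplyr::mutate(x$data, p = .data$n_chose / .data$n_total)
  grid <- tibble::tibble(
    level = seq(min(d$level), max(d$level), length.out = 200)
  )
  grid$p <- quick_pf(grid$level, x$alpha, x$beta, x$gamma, x$lambda)
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = pse(x), linetype = "dotted",
                        colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "variable luminance (cd/m²)",
                  y = "proportion chosen",
                  title = sprintf("PSE = %.3g cd/m²", pse(x))) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement plot
#'
#' @param data,first,second As in [bland_altman()].
#' @return A ggplot with the mean-difference and 1.96 SD limit lines.
#' @export
plot_bland_altman <- function(data, first, second) {
  a <- dplyr::pull(data, {{ first }})
  b <- dplyr::pull(data, {{ second }})
  ba <- bland_altman(data, {{ first }}, {{ second }})
  d <- tibble::tibble(mean = (a + b) / 2, diff = b - a)
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(ba$mean_diff, ba$lo, ba$hi),
                        linetype = c("solid", "dotted", "dotted")) +
    ggplot2::labs(x = "mean of methods", y = "difference (second - first)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
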