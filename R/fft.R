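#' Integer-cycle analysis window
#'
#' The FFT window must span an integer number of tagging periods so the
#' tagging frequency falls exactly on a DFT bin (no spectral leakage with a
#' rectangular window). `t2 = t1 + cycles * period_s`.
#'
#' @param t1 Window start, seconds after stimulus onset.
#' @param period_s Tagging period (seconds), i.e. `2 * half_period_s`.
#' @param cycles Integer number of periods (>= 1), the rho of the windowing
#'   rule `t2 = t1 + period_s * rho`.
#' @return A `pftm_analysis_window` with `t1`, `t2`, `cycles`, `period_s`.
#' @examples
#' analysis_window(0.3, 0.567, 4)  # t2 = 2.568
#' @export
analysis_window <- function(t1, period_s, cycles) {
  assert_number(t1, "t1")
  assert_number(period_s, "period_s", 0, strict = TRUE)
  if (!is.numeric(cycles) || length(cycles) != 1L ||
      cycles != round(cycles) || cycles < 1) {
    abort("`cycles` must be an integer >= 1")
  }
  structure(
    list(t1 = t1, t2 = t1 + period_s * cycles,
         cycles = as.integer(cycles), period_s = period_s),
    class = "pftm_analysis_window"
  )
}

#' @export
print.pftm_analysis_window <- function(x, ...) {
  cat(sprintf("<analysis window> [%g, %g] s = %d cycle(s) of %g s\n",
              x$t1, x$t2, x$cycles, x$period_s))
  invisible(x)
}

# Extract the samples of `trace` falling in [t1, t2) and sanity-check the
# window/frequency geometry. Returns list(x, n, duration, rate).
window_samples <- function(times, values, window) {
  stopifnot(inherits(window, "pftm_analysis_window"))
  rate <- trace_rate(times)
  if (window$t1 < min(times) - 1e-9 || window$t2 > max(times) + 1 / rate + 1e-9) {
    abort(sprintf("analysis window [%g, %g] s exceeds the trace support [%g, %g] s",
                  window$t1, window$t2, min(times), max(times)))
  }
  sel <- times >= window$t1 - 1e-9 & times < window$t2 - 1e-9
  n <- sum(sel)
  if (n < 2L) abort("analysis window contains fewer than two samples")
  list(x = values[sel], n = n, duration = n / rate, rate = rate)
}

#' Single-bin DFT amplitude and phase
#'
#' Computes the single-sided amplitude and phase of a trace at one frequency
#' over an integer-cycle window. The frequency must fall on a DFT bin of the
#' window (`(t2 - t1) * freq` integer within 1e-6). Amplitude is
#' `2 |X_k| / N` for `k > 0` and `|X_0| / N` at 0 Hz, so a pure sinusoid of
#' amplitude A yields A at its bin and the 0 Hz bin equals the absolute
#' window mean. Phase follows the cosine convention referenced to the first
#' sample at or after `t1`, reported in degrees in (-180, 180].
#'
#' @param trace A data frame with a time column and a value column (e.g. one
#'   trial of a samples tibble, or one condition of [average_trials()]).
#' @param window An [analysis_window()].
#' @param freq Frequency in Hz at which to evaluate.
#' @param time,value Names of the time and value columns (defaults
#'   `"time_s"` and the first of `"pupil"`/`"mean"` present).
#' @return A one-row tibble: `freq`, `amplitude`, `phase_deg`, `n`.
#' @export
fft_component <- function(trace, window, freq,
                          time = "time_s", value = NULL) {
  value <- value %||% intersect(c("pupil", "mean"), names(trace))[1]
  if (is.na(value) || !all(c(time, value) %in% names(trace))) {
    abort("`trace` must contain the time and value columns")
  }
  assert_number(freq, "freq", 0)
  ws <- window_samples(trace[[time]], trace[[value]], window)
  kf <- (window$t2 - window$t1) * freq
  if (abs(kf - round(kf)) > 1e-6) {
    abort(sprintf(
      "freq %g Hz is off the DFT grid of a %g s window (bin index %.6f is not an integer)",
      freq, window$t2 - window$t1, kf
    ))
  }
  k <- as.integer(round(kf))
  if (k > floor(ws$n / 2)) abort("freq is above the Nyquist frequency of the window")
  X <- fft(ws$x)[k + 1L]
  amp <- if (k == 0L) Mod(X) / ws$n else 2 * Mod(X) / ws$n
  tibble::tibble(
    freq = freq,
    amplitude = amp,
    phase_deg = wrap_degrees(Arg(X) * 180 / pi),
    n = ws$n
  )
}

#' Single-sided amplitude spectrum over a window
#'
#' All on-grid bins from 0 Hz up to `fmax`, with the scaling and phase
#' conventions of [fft_component()].
#'
#' @inheritParams fft_component
#' @param fmax Highest frequency to report (<= Nyquist).
#' @return A tibble with one row per bin: `freq`, `amplitude`, `phase_deg`.
#' @export
spectrum <- function(trace, window, fmax,
                     time = "time_s", value = NULL) {
  value <- value %||% intersect(c("pupil", "mean"), names(trace))[1]
  ws <- window_samples(trace[[time]], trace[[value]], window)
  if (fmax > ws$rate / 2 + 1e-9) abort("`fmax` exceeds the Nyquist frequency")
  X <- fft(ws$x)
  T <- ws$duration
  kmax <- min(floor(fmax * T + 1e-9), floor(ws$n / 2))
  k <- 0:kmax
  amp <- Mod(X[k + 1L]) / ws$n
  amp[k > 0] <- 2 * amp[k > 0]
  tibble::tibble(
    freq = k / T,
    amplitude = amp,
    phase_deg = wrap_degrees(Arg(X[k + 1L]) * 180 / pi)
  )
}

#' Tagging-frequency results per condition
#'
#' For each condition average, evaluates the 0 Hz (mean) amplitude and the
#' amplitude and phase at the session's tagging frequency over the given
#' integer-cycle window.
#'
#' @param averages Output of [average_trials()].
#' @param config A [session_config()]; supplies the tagging frequency.
#' @param window An [analysis_window()] whose period matches the session's.
#' @return A tibble with one row per condition: `condition`,
#'   `mean_amplitude`, `tag_amplitude`, `tag_phase_deg`, `n_trials`.
#' @export
tag_table <- function(averages, config, window) {
  stopifnot(inherits(config, "pftm_session_config"),
            inherits(window, "pftm_analysis_window"))
  if (abs(window$period_s - config$period_s) > 1e-9) {
    warn("analysis window period differs from the session's tagging period")
  }
  f_tag <- 1 / window$period_s
  out <- lapply(split(averages, averages$condition), function(g) {
    dc <- fft_component(g, window, 0, value = "mean")
    tg <- fft_component(g, window, f_tag, value = "mean")
    tibble::tibble(
      condition = g$condition[[1]],
      mean_amplitude = dc$amplitude,
      tag_amplitude = tg$amplitude,
      tag_phase_deg = tg$phase_deg,
      n_trials = g$n[[1]]
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$condition)
}

#' Normalise tagging amplitudes to the largest
#'
#' @param results A [tag_table()] tibble (or any tibble with a
#'   `tag_amplitude` column).
#' @return The input with an added `norm_amplitude` column in \[0, 1\]; the
#'   largest amplitude maps to exactly 1.
#' @export
normalise_amplitudes <- function(results) {
  a <- results$tag_amplitude
  if (is.null(a) || !length(a)) abort("`results` must contain `tag_amplitude`")
  if (anyNA(a) || any(a < 0)) abort("amplitudes must be finite and >= 0")
  mx <- max(a)
  if (mx <= 0) abort("cannot normalise: all amplitudes are zero")
  dplyr::mutate(results, norm_amplitude = .data$tag_amplitude / mx)
}
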