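#' Locate the amplitude minimum with a smoothing spline
#'
#' Fits a cubic smoothing spline (smoothing parameter chosen by generalized
#' cross-validation) to tagging-frequency amplitude versus variable
#' luminance, and locates its minimum by dense grid search restricted to the
#' tested luminance range — the estimate never extrapolates. A minimum
#' landing on the boundary of the tested range is reported but flagged
#' `boundary = TRUE`: the session design should be re-centred before
#' trusting a ratio from an edge.
#'
#' @param levels Variable luminances tested (cd/m^2), >= 4 distinct values.
#' @param amplitudes Tagging-frequency amplitudes at those levels (>= 0).
#' @param grid_n Number of grid points for the minimum search (>= 1000).
#' @return A `pftm_min_fit`: list with `min_luminance`, `min_amplitude`,
#'   `boundary`, `raw_argmin` (tested level with the smallest raw
#'   amplitude), `df` (equivalent degrees of freedom of the spline), and
#'   `curve`, a tibble of the fitted curve on the search grid.
#' @export
fit_minimum <- function(levels, amplitudes, grid_n = 1001) {
  if (length(levels) != length(amplitudes)) {
    abort("`levels` and `amplitudes` must have equal length")
  }
  if (length(unique(levels)) < 4) {
    abort("need at least 4 distinct luminance levels to fit a tuning curve")
  }
  if (anyNA(levels) || anyNA(amplitudes) || !all(is.finite(amplitudes))) {
    abort("levels and amplitudes must be finite")
  }
  if (any(amplitudes < 0)) abort("amplitudes must be >= 0")
  if (grid_n < 1000) abort("`grid_n` must be >= 1000")
  ord <- order(levels)
  levels <- levels[ord]; amplitudes <- amplitudes[ord]
  fit <- smooth.spline(levels, amplitudes, cv = FALSE)
  grid <- seq(min(levels), max(levels), length.out = grid_n)
  pred <- predict(fit, grid)$y
  i <- which.min(pred)
  structure(
    list(
      min_luminance = grid[[i]],
      min_amplitude = pred[[i]],
      boundary = i == 1L || i == grid_n,
      raw_argmin = levels[[which.min(amplitudes)]],
      df = fit$df,
      curve = tibble::tibble(level = grid, amplitude = pred)
    ),
    class = "pftm_min_fit"
  )
}

#' @export
print.pftm_min_fit <- function(x, ...) {
  cat(sprintf("<amplitude minimum> %.4g cd/m^2 (fitted, df = %.2f)%s; raw argmin %.4g\n",
              x$min_luminance, x$df,
              if (x$boundary) " [unbracketed: on range boundary]" else "",
              x$raw_argmin))
  invisible(x)
}

#' Detect the phase inversion across the equiluminant point
#'
#' As the variable luminance crosses the observer's equiluminance point the
#' pupil oscillation reverses sign, an approximately 180 degree phase flip.
#' Phases are unwrapped over sorted levels; the low and high plateaus are
#' estimated as medians over the first and last quartile of levels; the
#' transition start (end) is the last (first) level within 20 degrees of its
#' plateau, and the midpoint is the level at which the unwrapped phase
#' crosses the mean of the two plateaus, linearly interpolated between the
#' bracketing levels.
#'
#' @param levels Variable luminances (cd/m^2).
#' @param phases_deg Tagging-frequency phases at those levels (degrees).
#' @return A one-row tibble: `found`, `start`, `midpoint`, `end`,
#'   `plateau_lo`, `plateau_hi`, `excursion` (degrees). When the total
#'   excursion is below 90 degrees there is no usable transition and
#'   `found = FALSE` with NA landmarks.
#' @export
detect_phase_transition <- function(levels, phases_deg) {
  if (length(levels) != length(phases_deg)) {
    abort("`levels` and `phases_deg` must have equal length")
  }
  if (length(levels) < 4) abort("need at least 4 levels to detect a phase transition")
  ord <- order(levels)
  L <- levels[ord]
  ph <- unwrap_degrees(phases_deg[ord])
  n <- length(L)
  q <- max(1L, floor(n / 4))
  plateau_lo <- median(ph[seq_len(q)])
  plateau_hi <- median(ph[seq.int(n - q + 1L, n)])
  excursion <- abs(plateau_hi - plateau_lo)
  none <- tibble::tibble(found = FALSE, start = NA_real_, midpoint = NA_real_,
                         end = NA_real_, plateau_lo = plateau_lo,
                         plateau_hi = plateau_hi, excursion = excursion)
  if (excursion < 90) return(none)
  mid_phase <- (plateau_lo + plateau_hi) / 2
  sign_dir <- sign(plateau_hi - plateau_lo)
  crossed <- sign_dir * (ph - mid_phase) >= 0
  j <- which(crossed)[1]
  if (is.na(j) || j == 1L) return(none)
  midpoint <- L[j - 1] + (L[j] - L[j - 1]) *
    (mid_phase - ph[j - 1]) / (ph[j] - ph[j - 1])
  near_lo <- abs(ph - plateau_lo) <= 20
  near_hi <- abs(ph - plateau_hi) <= 20
  start <- if (any(near_lo & L < midpoint)) max(L[near_lo & L < midpoint]) else L[1]
  end <- if (any(near_hi & L > midpoint)) min(L[near_hi & L > midpoint]) else L[n]
  tibble::tibble(found = TRUE, start = start, midpoint = midpoint, end = end,
                 plateau_lo = plateau_lo, plateau_hi = plateau_hi,
                 excursion = excursion)
}

#' Fixed-to-variable luminance ratio
#'
#' The observer's equiluminance setting is reported as the ratio of the
#' fixed colour's luminance to the variable luminance minimising the tagged
#' pupil oscillation (e.g. red : green).
#'
#' @param fixed_luminance,min_luminance Luminances in cd/m^2, both > 0.
#' @return `fixed_luminance / min_luminance`.
#' @export
luminance_ratio <- function(fixed_luminance, min_luminance) {
  assert_number(fixed_luminance, "fixed_luminance", 0, strict = TRUE)
  assert_number(min_luminance, "min_luminance", 0, strict = TRUE)
  fixed_luminance / min_luminance
}

#' Estimate the equiluminance point from tagging results
#'
#' Combines the smoothing-spline amplitude minimum ([fit_minimum()]) with
#' the phase inversion ([detect_phase_transition()]): the estimate is
#' `confirmed` when the spline minimum lies within `phase_tolerance` of the
#' phase-transition midpoint, and a `combined_luminance` (the unweighted
#' mean of the two landmarks) is reported whenever both exist.
#'
#' @param results A [tag_table()] tibble covering >= 4 conditions.
#' @param config The [session_config()]; supplies the fixed luminance.
#' @param phase_tolerance Agreement tolerance in cd/m^2; defaults to one
#'   luminance step (the median spacing of the tested levels).
#' @return A `pftm_estimate` list: `min_luminance`, `ratio`,
#'   `phase_transition` (tibble row from [detect_phase_transition()]),
#'   `confirmed` (NA when no transition was found), `combined_luminance`,
#'   `combined_ratio`, `boundary`, `raw_argmin`, `fit` (the `pftm_min_fit`),
#'   `fixed_luminance`, `phase_tolerance`.
#' @export
estimate_equiluminance <- function(results, config, phase_tolerance = NULL) {
  stopifnot(inherits(config, "pftm_session_config"))
  if (nrow(results) < 4) abort("need results for at least 4 conditions")
  phase_tolerance <- phase_tolerance %||% median(diff(sort(results$condition)))
  fit <- fit_minimum(results$condition, results$tag_amplitude)
  pt <- detect_phase_transition(results$condition, results$tag_phase_deg)
  confirmed <- if (pt$found) abs(fit$min_luminance - pt$midpoint) <= phase_tolerance else NA
  combined <- if (pt$found) mean(c(fit$min_luminance, pt$midpoint)) else NA_real_
  structure(
    list(
      min_luminance = fit$min_luminance,
      ratio = luminance_ratio(config$fixed_luminance, fit$min_luminance),
      phase_transition = pt,
      confirmed = confirmed,
      combined_luminance = combined,
      combined_ratio = if (pt$found) config$fixed_luminance / combined else NA_real_,
      boundary = fit$boundary,
      raw_argmin = fit$raw_argmin,
      fit = fit,
      fixed_luminance = config$fixed_luminance,
      phase_tolerance = phase_tolerance
    ),
    class = "pftm_estimate"
  )
}

#' @export
print.pftm_estimate <- function(x, ...) {
  cat("<equiluminance estimate>\n")
  cat(sprintf("  amplitude minimum: %.4g cd/m^2%s (raw argmin %.4g)\n",
              x$min_luminance,
              if (x$boundary) " [unbracketed]" else "", x$raw_argmin))
  cat(sprintf("  fixed : variable ratio: %.3f\n", x$ratio))
  if (isTRUE(x$phase_transition$found)) {
    cat(sprintf("  phase transition: %.4g -> %.4g cd/m^2 (midpoint %.4g), %s by phase (tol %.3g)\n",
                x$phase_transition$start, x$phase_transition$end,
                x$phase_transition$midpoint,
                if (isTRUE(x$confirmed)) "confirmed" else "NOT confirmed",
                x$phase_tolerance))
    cat(sprintf("  combined (amplitude+phase) estimate: %.4g cd/m^2 (ratio %.3f)\n",
                x$combined_luminance, x$combined_ratio))
  } else {
    cat("  no phase transition detected (excursion < 90 deg)\n")
  }
  invisible(x)
}

#' Run the full tagging analysis on a session
#'
#' The standard pipeline: Gaussian smoothing, per-trial baseline correction,
#' per-condition averaging, single-bin FFT at 0 Hz and at the tagging
#' frequency over an integer-cycle window, then spline-minimum estimation
#' confirmed by the phase inversion.
#'
#' @param samples Pupil samples tibble (`trial_id`, `condition`, `time_s`,
#'   `pupil`).
#' @param config The [session_config()].
#' @param t1 Window start in seconds, or `"auto"`: the first colour-reversal
#'   boundary at or after 1 s post-onset (pupil onset dynamics are excluded).
#' @param cycles Number of tagging periods to analyse; default as many as
#'   fit between `t1` and the trial end.
#' @param smooth_ms Gaussian smoothing width (ms); 0 disables.
#' @param baseline `"window_mean"` (mean over the FFT window, the default)
#'   or `"prestim"`.
#' @param prestim_window Baseline window for `"prestim"` mode.
#' @param phase_tolerance Passed to [estimate_equiluminance()].
#' @return A `pftm_analysis` list: `results` (the [tag_table()]), `estimate`
#'   (the [estimate_equiluminance()]), `window`, `averages`, `config`.
#' @examples
#' cfg <- session_config(variable_levels = seq(6, 36, length.out = 8),
#'                       repeats = 2)
#' mod <- observer_model(gain = 1, noise_sd = 0)
#' s <- simulate_session(cfg, mod, seed = 7, rate = 250)
#' fit <- pftm_analyze(s, cfg)
#' fit$estimate$ratio
#' @export
pftm_analyze <- function(samples, config,
                         t1 = "auto", cycles = NULL,
                         smooth_ms = 30,
                         baseline = c("window_mean", "prestim"),
                         prestim_window = c(-0.1, 0.1),
                         phase_tolerance = NULL) {
  baseline <- match.arg(baseline)
  validate_session(samples, config)
  if (identical(t1, "auto")) {
    t1 <- config$half_period_s * ceiling(1.0 / config$half_period_s)
  }
  cycles <- cycles %||% floor((config$trial_duration_s - t1) / config$period_s + 1e-9)
  if (cycles < 1) abort("no full tagging cycle fits between `t1` and the trial end")
  window <- analysis_window(t1, config$period_s, cycles)
  pre <- if (smooth_ms > 0) smooth_pupil(samples, smooth_ms) else samples
  pre <- if (baseline == "window_mean") {
    baseline_correct(pre, "window_mean", window)
  } else {
    baseline_correct(pre, "prestim", prestim_window)
  }
  averages <- average_trials(pre)
  results <- tag_table(averages, config, window)
  estimate <- estimate_equiluminance(results, config, phase_tolerance)
  structure(
    list(results = results, estimate = estimate, window = window,
         averages = averages, config = config),
    class = "pftm_analysis"
  )
}

#' @export
print.pftm_analysis <- function(x, ...) {
  cat(sprintf("<pftm analysis> %d conditions, window [%g, %g] s (%d cycles)\n",
              nrow(x$results), x$window$t1, x$window$t2, x$window$cycles))
  print(x$estimate)
  invisible(x)
}
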