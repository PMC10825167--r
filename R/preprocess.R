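# Truncated, unit-sum Gaussian smoothing kernel.
# Total width `window_ms`, sigma = window_ms / 5, truncated at +/- window_ms/2,
# sampled on the trace's grid. Returns numeric(0) when the window is
# degenerate (identity smoothing).
gaussian_kernel <- function(window_ms, rate) {
  if (window_ms < 0) abort("`window_ms` must be >= 0")
  half_w_s <- window_ms / 2000
  h <- floor(half_w_s * rate)
  if (window_ms == 0 || h < 1) return(numeric(0))
  tau <- (-h:h) / rate
  sigma <- window_ms / 5000
  k <- exp(-0.5 * (tau / sigma)^2)
  k / sum(k)
}

# Convolve with a symmetric kernel, shrinking (and renormalising) the window
# at the boundaries so output length equals input length.
convolve_shrink <- function(x, k) {
  n <- length(x)
  if (!length(k)) return(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  h <- (length(k) - 1L) / 2L
  idx <- (h + 1L):(h + n)
  num[idx] / den[idx]
}

# Apply f(times, values) -> values trial-by-trial over the long samples
# tibble; rows keep their original order within each trial.
per_trial_modify <- function(samples, f) {
  if (!"trial_id" %in% names(samples)) {
    samples$pupil <- f(samples$time_s, samples$pupil)
    return(samples)
  }
  groups <- split(seq_len(nrow(samples)), samples$trial_id)
  pupil <- samples$pupil
  for (rows in groups) {
    pupil[rows] <- f(samples$time_s[rows], samples$pupil[rows])
  }
  samples$pupil <- pupil
  samples
}

#' Gaussian smoothing of pupil traces
#'
#' Convolves each trial's trace with a truncated, unit-sum Gaussian kernel of
#' total width `window_ms` (sigma = `window_ms / 5`, truncated at +/-
#' `window_ms / 2`). Output length and time axis are unchanged; at the trace
#' boundaries the kernel shrinks to the available samples and is
#' renormalised. `window_ms = 0` (or a window shorter than one sample) is the
#' identity.
#'
#' @param samples Pupil samples tibble.
#' @param window_ms Total kernel width in milliseconds (default 30, the
#'   standard light pre-filter for pupillometry at 1 kHz).
#' @return The samples tibble with smoothed `pupil`.
#' @export
smooth_pupil <- function(samples, window_ms = 30) {
  assert_samples(samples, require_trial = FALSE)
  if (!nrow(samples)) abort("cannot smooth an empty trace")
  per_trial_modify(samples, function(t, x) {
    convolve_shrink(x, gaussian_kernel(window_ms, trace_rate(t)))
  })
}

#' Baseline-correct pupil traces
#'
#' Subtracts, per trial, the scalar mean pupil value over a reference time
#' window. Two conventions are supported: `"prestim"` uses a short window
#' centred on stimulus onset (default -0.1 to +0.1 s; widen to +/- 0.2 s for
#' non-human primate sessions), and `"window_mean"` uses the same window as
#' the subsequent FFT, which by construction zeroes the corrected trace's
#' mean over that window (and hence its 0 Hz amplitude).
#'
#' @param samples Pupil samples tibble.
#' @param mode `"prestim"` or `"window_mean"`.
#' @param window Length-2 numeric `c(a, b)` in seconds, or an
#'   [analysis_window()] (required for `"window_mean"`). Defaults to
#'   `c(-0.1, 0.1)` for `"prestim"`.
#' @return The samples tibble with baseline-corrected `pupil`.
#' @export
baseline_correct <- function(samples,
                             mode = c("window_mean", "prestim"),
                             window = NULL) {
  assert_samples(samples, require_trial = FALSE)
  mode <- match.arg(mode)
  if (is.null(window)) {
    if (mode == "prestim") window <- c(-0.1, 0.1)
    else abort("mode = \"window_mean\" needs the FFT analysis window")
  }
  if (inherits(window, "pftm_analysis_window")) {
    window <- c(window$t1, window$t2)
  }
  if (!is.numeric(window) || length(window) != 2L || window[2] <= window[1]) {
    abort("`window` must be c(a, b) seconds with a < b")
  }
  per_trial_modify(samples, function(t, x) {
    sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
    if (!any(sel)) {
      abort(sprintf("baseline window [%g, %g] s contains no samples of a trace spanning [%g, %g] s",
                    window[1], window[2], min(t), max(t)))
    }
    x - mean(x[sel])
  })
}

#' Average trials within each condition
#'
#' Pointwise mean and standard error (SD / sqrt(n)) across the repeats of
#' each condition. All trials of a condition must share the same time grid
#' and sampling rate; mismatched grids are an error, never silently
#' resampled.
#'
#' @param samples Pupil samples tibble with `trial_id`, `condition`,
#'   `time_s`, `pupil`.
#' @return A tibble with columns `condition`, `time_s`, `mean`, `sem`, `n`
#'   (trials averaged); `sem` is all-zero when `n = 1`.
#' @export
average_trials <- function(samples) {
  assert_samples(samples)
  out <- lapply(split(samples, samples$condition), function(g) {
    tr <- lapply(split(g, g$trial_id), function(x) x[order(x$time_s), ])
    t0 <- tr[[1]]$time_s
    trace_rate(t0)
    for (x in tr[-1]) {
      if (length(x$time_s) != length(t0) || any(abs(x$time_s - t0) > 1e-9)) {
        abort(sprintf(
          "trials of condition %g do not share a common time grid; resample explicitly first",
          g$condition[[1]]
        ))
      }
    }
    m <- vapply(tr, function(x) x$pupil, numeric(length(t0)))
    m <- matrix(m, nrow = length(t0))
    n <- ncol(m)
    mu <- rowMeans(m)
    sem <- if (n == 1L) rep(0, length(t0)) else {
      sqrt(rowSums((m - mu)^2) / (n - 1)) / sqrt(n)
    }
    tibble::tibble(condition = g$condition[[1]], time_s = t0,
                   mean = mu, sem = sem, n = n)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$condition, .data$time_s)
}

#' Downsample pupil traces by integer decimation
#'
#' Anti-alias smooths with a centred moving average the length of the
#' decimation factor, then keeps every factor-th sample. The decimation
#' factor `rate / target_hz` must be an integer; slow tagging components
#' (~1.77 Hz) pass essentially unattenuated.
#'
#' @param samples Pupil samples tibble.
#' @param target_hz New sampling rate; must divide the current rate.
#' @return The decimated samples tibble.
#' @export
downsample <- function(samples, target_hz) {
  assert_samples(samples, require_trial = FALSE)
  assert_number(target_hz, "target_hz", 0, strict = TRUE)
  one <- function(g) {
    rate <- trace_rate(g$time_s)
    m <- rate / target_hz
    if (m < 1 - 1e-9) abort("`target_hz` exceeds the current sampling rate")
    if (abs(m - round(m)) > 1e-6) {
      abort(sprintf("rate %g Hz is not an integer multiple of target %g Hz",
                    rate, target_hz))
    }
    m <- as.integer(round(m))
    if (m == 1L) return(g)
    k <- rep(1 / m, m + 1 - m %% 2)  # odd-length centred boxcar
    k <- k / sum(k)
    sm <- convolve_shrink(g$pupil, k)
    keep <- seq(1L, nrow(g), by = m)
    g <- g[keep, , drop = FALSE]
    g$pupil <- sm[keep]
    g
  }
  if (!"trial_id" %in% names(samples)) return(one(samples))
  dplyr::bind_rows(lapply(split(samples, samples$trial_id), one))
}
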