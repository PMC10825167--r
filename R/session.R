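#' Define a frequency-tagging session
#'
#' A session alternates a disc between a fixed colour/luminance and one of
#' several variable luminances every `half_period_s` seconds, so the stimulus
#' "tags" the pupil at `1 / (2 * half_period_s)` Hz. The defaults reproduce
#' the standard protocol: 0.283 s per colour (34 frames at 120 Hz refresh),
#' giving a tagging frequency of about 1.77 Hz, 3.5 s trials, and at least
#' five repeats per variable level.
#'
#' @param fixed_colour,variable_colour Colour labels (e.g. `"red"`, `"green"`).
#' @param fixed_luminance Luminance of the fixed colour in cd/m^2.
#' @param variable_levels Numeric vector of at least 3 variable luminances
#'   (cd/m^2); stored sorted ascending.
#' @param half_period_s Duration each colour is shown (seconds).
#' @param refresh_hz Display refresh rate (Hz).
#' @param frames_per_half_period Frames per colour presentation; must agree
#'   with `half_period_s * refresh_hz` within 1 ms.
#' @param repeats Planned repeats per variable level (>= 1).
#' @param trial_duration_s Stimulation time per trial (seconds).
#'
#' @return An object of class `pftm_session_config`: a list with the inputs
#'   plus the derived `period_s = 2 * half_period_s` and
#'   `tag_frequency_hz = 1 / period_s`.
#' @examples
#' cfg <- session_config(variable_levels = seq(0, 41.2, length.out = 10))
#' cfg$tag_frequency_hz
#' @export
session_config <- function(fixed_colour = "red",
                           fixed_luminance = 21.04,
                           variable_colour = "green",
                           variable_levels,
                           half_period_s = 0.283,
                           refresh_hz = 120,
                           frames_per_half_period = 34,
                           repeats = 5,
                           trial_duration_s = 3.5) {
  assert_number(fixed_luminance, "fixed_luminance", 0, strict = TRUE)
  assert_number(half_period_s, "half_period_s", 0, strict = TRUE)
  assert_number(refresh_hz, "refresh_hz", 0, strict = TRUE)
  assert_number(trial_duration_s, "trial_duration_s", 0, strict = TRUE)
  if (!is.numeric(repeats) || repeats < 1 || repeats != round(repeats)) {
    abort("`repeats` must be an integer >= 1")
  }
  if (!is.numeric(variable_levels) || length(variable_levels) < 3 ||
      anyNA(variable_levels) || any(variable_levels < 0)) {
    abort("`variable_levels` must be >= 3 finite luminances, all >= 0 cd/m^2")
  }
  if (anyDuplicated(variable_levels)) {
    abort("`variable_levels` must be distinct")
  }
  if (abs(frames_per_half_period / refresh_hz - half_period_s) > 1e-3) {
    abort(sprintf(
      "frames_per_half_period / refresh_hz = %.4f s disagrees with half_period_s = %.4f s (tolerance 1 ms)",
      frames_per_half_period / refresh_hz, half_period_s
    ))
  }
  structure(
    list(
      fixed_colour = fixed_colour,
      fixed_luminance = fixed_luminance,
      variable_colour = variable_colour,
      variable_levels = sort(variable_levels),
      half_period_s = half_period_s,
      refresh_hz = refresh_hz,
      frames_per_half_period = frames_per_half_period,
      repeats = as.integer(repeats),
      trial_duration_s = trial_duration_s,
      period_s = 2 * half_period_s,
      tag_frequency_hz = 1 / (2 * half_period_s)
    ),
    class = "pftm_session_config"
  )
}

#' @export
print.pftm_session_config <- function(x, ...) {
  cat("<pftm session>\n")
  cat(sprintf("  fixed:    %s at %.4g cd/m^2\n", x$fixed_colour, x$fixed_luminance))
  cat(sprintf("  variable: %s, %d levels in [%.4g, %.4g] cd/m^2\n",
              x$variable_colour, length(x$variable_levels),
              min(x$variable_levels), max(x$variable_levels)))
  cat(sprintf("  half-period %.3f s (%d frames @ %g Hz) -> tagging %.3f Hz\n",
              x$half_period_s, x$frames_per_half_period, x$refresh_hz,
              x$tag_frequency_hz))
  cat(sprintf("  %d repeats/level, %.2f s trials\n", x$repeats, x$trial_duration_s))
  invisible(x)
}

# Match a vector of conditions against configured levels (1e-9 tolerance);
# returns the index into config$variable_levels or NA.
match_level <- function(condition, levels, tol = 1e-9) {
  vapply(condition, function(ci) {
    hit <- which(abs(levels - ci) <= tol)
    if (length(hit)) hit[[1L]] else NA_integer_
  }, integer(1))
}

#' Validate a session's trials against its configuration
#'
#' Checks that every trial carries exactly one condition label, that every
#' condition is one of the configured variable levels (matched with 1e-9
#' cd/m^2 tolerance), and that every level was tested at least once.
#'
#' @param samples Tibble of pupil samples with columns `trial_id`,
#'   `condition`, `time_s`, `pupil` (long format, one row per sample).
#' @param config A [session_config()].
#'
#' @return A tibble with one row per condition: `condition`, `n_trials`, and
#'   a `trial_ids` list-column of the trials recorded at that level.
#' @examples
#' cfg <- session_config(variable_levels = c(10, 20, 30), repeats = 1)
#' mod <- observer_model(noise_sd = 0)
#' s <- simulate_session(cfg, mod, seed = 1, rate = 100)
#' validate_session(s, cfg)
#' @export
validate_session <- function(samples, config) {
  assert_samples(samples)
  stopifnot(inherits(config, "pftm_session_config"))
  per_trial <- dplyr::distinct(samples, .data$trial_id, .data$condition)
  dup <- per_trial$trial_id[duplicated(per_trial$trial_id)]
  if (length(dup)) {
    abort(sprintf("trial(s) %s carry more than one condition label",
                  paste(unique(dup), collapse = ", ")))
  }
  idx <- match_level(per_trial$condition, config$variable_levels)
  if (anyNA(idx)) {
    bad <- unique(per_trial$condition[is.na(idx)])
    abort(sprintf("condition(s) not in configured variable levels: %s",
                  paste(format(bad), collapse = ", ")))
  }
  grouped <- per_trial |>
    dplyr::mutate(condition = config$variable_levels[idx]) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      trial_ids = list(.data$trial_id),
      .groups = "drop"
    )
  untested <- setdiff(seq_along(config$variable_levels),
                      match_level(grouped$condition, config$variable_levels))
  if (length(untested)) {
    abort(sprintf("no trials recorded for level(s): %s",
                  paste(format(config$variable_levels[untested]), collapse = ", ")))
  }
  grouped
}
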