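#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft sd median quantile qt pt dbinom rnorm rbinom optim
#'   smooth.spline predict dgamma qgamma nextn
NULL

# Wrap angles in degrees to (-180, 180].
wrap_degrees <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Unwrap a sequence of angles (degrees) so adjacent jumps never exceed 180.
unwrap_degrees <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  step <- -360 * round(d / 360)
  x + c(0, cumsum(step))
}

# Sampling rate from a strictly increasing, uniform time grid (seconds).
# Gaps and jitter are contract violations, not silently repaired.
trace_rate <- function(times, tol = 1e-9) {
  if (length(times) < 2L) {
    abort("a pupil trace needs at least two samples to define a rate")
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    abort("trace times must be strictly increasing")
  }
  if (max(dt) - min(dt) > tol) {
    abort(sprintf(
      "trace time grid is not uniform (spacing varies by %.3g s, tolerance %.1g s)",
      max(dt) - min(dt), tol
    ))
  }
  1 / mean(dt)
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) {
    abort(sprintf("`%s` must be > %g (got %g)", name, lower, x))
  }
  if (!strict && x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g)", name, lower, x))
  }
  invisible(x)
}

assert_samples <- function(samples, require_trial = TRUE) {
  needed <- c("condition", "time_s", "pupil")
  if (require_trial) needed <- c("trial_id", needed)
  missing <- setdiff(needed, names(samples))
  if (length(missing)) {
    abort(paste0(
      "samples are missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(samples)
}

# Pupil unit bookkeeping: an attribute, defaulting to arbitrary units.
pupil_unit <- function(samples) attr(samples, "pupil_unit") %||% "au"

set_pupil_unit <- function(samples, unit) {
  attr(samples, "pupil_unit") <- unit
  samples
}
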