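#' Synthetic pupil observer
#'
#' A generative stand-in for the reflexive pupil response to a
#' luminance-alternating disc. The perceived luminance of the variable
#' colour is `gain * L_v`; the drive is the difference between the perceived
#' stimulus luminance and the (physically fixed-equiluminant) background,
#' convolved with a sluggish gamma-shaped impulse response and delayed by a
#' neural latency. Higher perceived luminance constricts the pupil
#' (diameter decreases). The mean (baseline-offset) and oscillatory
#' components carry separate gains, and AR(1) Gaussian noise emulates slow
#' physiological pupil drift.
#'
#' Equiluminance holds when `gain * L_v = L_f`: the oscillatory drive then
#' vanishes, which is the ground truth the analysis pipeline must recover.
#'
#' @param gain Perceived-luminance multiplier for the variable colour
#'   (dimensionless, > 0); the simulated equiluminant level is
#'   `fixed_luminance / gain`.
#' @param k_dc Baseline-offset gain, mm per cd/m^2 of mean perceived
#'   difference from background.
#' @param k_osc Oscillation gain, mm per cd/m^2 of perceived difference.
#' @param latency Pure response delay in seconds (on top of the kernel's
#'   intrinsic lag; together they give the ~0.5-0.7 s apparent onset).
#' @param kernel_shape Shape of the gamma-density impulse response.
#' @param kernel_scale Scale (seconds) of the gamma kernel; default places
#'   the kernel peak at 0.45 s (`peak = (shape - 1) * scale`).
#' @param baseline_mm Resting pupil diameter (mm).
#' @param noise_sd Stationary SD of the additive AR(1) noise (mm).
#' @param ar1 Lag-one autocorrelation of the noise, in \[0, 1).
#' @return An `pftm_observer` list of the parameters.
#' @export
observer_model <- function(gain = 1,
                           k_dc = 0.01,
                           k_osc = 0.02,
                           latency = 0.2,
                           kernel_shape = 8,
                           kernel_scale = 0.45 / (kernel_shape - 1),
                           baseline_mm = 5,
                           noise_sd = 0.02,
                           ar1 = 0.97) {
  assert_number(gain, "gain", 0, strict = TRUE)
  assert_number(k_dc, "k_dc", 0)
  assert_number(k_osc, "k_osc", 0)
  assert_number(latency, "latency", 0)
  assert_number(kernel_shape, "kernel_shape", 0, strict = TRUE)
  assert_number(kernel_scale, "kernel_scale", 0, strict = TRUE)
  assert_number(noise_sd, "noise_sd", 0)
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must be in [0, 1)")
  structure(
    list(gain = gain, k_dc = k_dc, k_osc = k_osc, latency = latency,
         kernel_shape = kernel_shape, kernel_scale = kernel_scale,
         baseline_mm = baseline_mm, noise_sd = noise_sd, ar1 = ar1),
    class = "pftm_observer"
  )
}

#' @export
print.pftm_observer <- function(x, ...) {
  cat(sprintf(
    "<pupil observer> gain %.3g, k_dc %.3g, k_osc %.3g mm/(cd/m^2), latency %.2g s,\n  gamma kernel (shape %.3g, scale %.3g s), baseline %.3g mm, noise %.3g mm (AR1 %.3g)\n",
    x$gain, x$k_dc, x$k_osc, x$latency, x$kernel_shape, x$kernel_scale,
    x$baseline_mm, x$noise_sd, x$ar1))
  invisible(x)
}

#' Perceived luminance drive of the alternating disc
#'
#' The square-wave perceived luminance seen by the simulated observer: the
#' fixed luminance during the first half-period and `gain * condition`
#' during the second, alternating every `half_period_s`; before stimulus
#' onset (`t < 0`) the drive equals the background, which is physically
#' equiluminant with the fixed colour.
#'
#' @param config A [session_config()].
#' @param condition Variable luminance (cd/m^2).
#' @param model An [observer_model()].
#' @param t Times in seconds (vectorised).
#' @return Perceived luminance in cd/m^2 at each `t`.
#' @export
perceived_drive <- function(config, condition, model, t) {
  stopifnot(inherits(config, "pftm_session_config"),
            inherits(model, "pftm_observer"))
  lv <- model$gain * condition
  half <- config$half_period_s
  out <- ifelse(t < 0, config$fixed_luminance,
                ifelse(floor(t / half) %% 2 == 0, config$fixed_luminance, lv))
  out
}

# Causal gamma-density impulse response sampled at `rate`, unit sum.
pupil_kernel <- function(model, rate) {
  support <- qgamma(0.999, model$kernel_shape, scale = model$kernel_scale)
  tau <- seq(0, support, by = 1 / rate)
  k <- dgamma(tau, model$kernel_shape, scale = model$kernel_scale)
  k / sum(k)
}

causal_conv <- function(x, k) {
  n <- length(x)
  nf <- stats::nextn(n + length(k) - 1L)
  y <- Re(fft(fft(c(x, numeric(nf - n))) *
                fft(c(k, numeric(nf - length(k)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

# Deterministic (noise-free) response of one condition; shared by all its
# repeats within a session.
deterministic_trace <- function(config, condition, model, rate, prestim_s) {
  n <- as.integer(round((prestim_s + config$trial_duration_s) * rate))
  t <- (seq_len(n) - 1L) / rate - prestim_s
  drive <- perceived_drive(config, condition, model, t)
  diffd <- drive - config$fixed_luminance
  mean_part <- numeric(n)
  mean_part[t >= 0] <- (model$gain * condition - config$fixed_luminance) / 2
  osc_part <- diffd - mean_part
  k <- pupil_kernel(model, rate)
  resp <- model$k_dc * causal_conv(mean_part, k) +
    model$k_osc * causal_conv(osc_part, k)
  lag <- as.integer(round(model$latency * rate))
  if (lag > 0) resp <- c(numeric(lag), resp[seq_len(n - lag)])
  list(time_s = t, pupil = model$baseline_mm - resp)
}

ar1_noise <- function(n, model, seed) {
  set.seed(seed)
  e <- rnorm(n, 0, model$noise_sd * sqrt(1 - model$ar1^2))
  as.numeric(stats::filter(e, model$ar1, method = "recursive"))
}

#' Simulate one pupil trial
#'
#' Builds the trace `baseline - k_dc * (mean drive difference (*) kernel) -
#' k_osc * (oscillatory drive difference (*) kernel)`, delayed by the
#' observer's latency, plus AR(1) Gaussian noise. `(*)` is causal
#' convolution with the gamma kernel. Identical seeds give identical
#' traces.
#'
#' @inheritParams perceived_drive
#' @param seed Integer seed for the trial's noise.
#' @param trial_id Integer trial identifier.
#' @param rate Sampling rate in Hz (default 1000, typical of research
#'   eye trackers).
#' @param prestim_s Seconds of pre-onset fixation recorded (negative times).
#' @return A samples tibble: `trial_id`, `condition`, `time_s`, `pupil`
#'   (mm).
#' @export
simulate_trial <- function(config, condition, model, seed,
                           trial_id = 1L, rate = 1000, prestim_s = 0.5) {
  stopifnot(inherits(config, "pftm_session_config"),
            inherits(model, "pftm_observer"))
  det <- deterministic_trace(config, condition, model, rate, prestim_s)
  pupil <- det$pupil
  if (model$noise_sd > 0) {
    pupil <- pupil + ar1_noise(length(pupil), model, seed)
  }
  set_pupil_unit(
    tibble::tibble(trial_id = as.integer(trial_id), condition = condition,
                   time_s = det$time_s, pupil = pupil),
    "mm"
  )
}

#' Simulate a full tagging session
#'
#' `repeats x levels` trials in a fully randomised order. Per-trial noise
#' seeds are drawn once from the master-seeded RNG (`sample.int` after
#' `set.seed(seed)`), so a session is reproducible from its master seed
#' alone and trials are mutually independent.
#'
#' @inheritParams simulate_trial
#' @param seed Master seed for trial order and per-trial noise.
#' @return A samples tibble with `repeats * length(variable_levels)` trials;
#'   `trial_id` is presentation order.
#' @examples
#' cfg <- session_config(variable_levels = c(10, 20, 30), repeats = 1)
#' s <- simulate_session(cfg, observer_model(noise_sd = 0), seed = 1, rate = 100)
#' dplyr::count(s, condition)
#' @export
simulate_session <- function(config, model, seed, rate = 1000, prestim_s = 0.5) {
  stopifnot(inherits(config, "pftm_session_config"))
  conditions <- rep(config$variable_levels, config$repeats)
  n_trials <- length(conditions)
  set.seed(seed)
  order <- sample.int(n_trials)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  conditions <- conditions[order]
  det <- lapply(config$variable_levels, deterministic_trace,
                config = config, model = model,
                rate = rate, prestim_s = prestim_s)
  names(det) <- sprintf("%.17g", config$variable_levels)
  out <- purrr::map(seq_len(n_trials), function(i) {
    d <- det[[sprintf("%.17g", conditions[[i]])]]
    pupil <- d$pupil
    if (model$noise_sd > 0) {
      pupil <- pupil + ar1_noise(length(pupil), model, trial_seeds[[i]])
    }
    tibble::tibble(trial_id = i, condition = conditions[[i]],
                   time_s = d$time_s, pupil = pupil)
  })
  set_pupil_unit(dplyr::bind_rows(out), "mm")
}

#' Simulate 2AFC minimum-motion responses
#'
#' Binomial draws from a Quick-function observer: at each level the
#' probability of choosing the designated direction is
#' [quick_pf()]`(level, alpha, beta, gamma, lambda)`.
#'
#' @param levels Stimulus levels (cd/m^2).
#' @param alpha,beta,gamma,lambda Generating Quick parameters.
#' @param n_per_level Trials per level (>= 1).
#' @param seed Integer seed.
#' @return A response tibble: `level`, `n_chose`, `n_total`.
#' @export
simulate_2afc <- function(levels, alpha, beta, gamma = 0, lambda = 0,
                          n_per_level = 10, seed = 1) {
  if (n_per_level < 1) abort("`n_per_level` must be >= 1")
  p <- quick_pf(levels, alpha, beta, gamma, lambda)
  set.seed(seed)
  tibble::tibble(
    level = levels,
    n_chose = rbinom(length(levels), n_per_level, p),
    n_total = as.integer(n_per_level)
  )
}
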