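# Shared fixtures: small, fast sessions and an independent DFT oracle.

# Direct single-frequency DFT sum over [t1, t2): the O(N) reference the
# fft()-based implementation is checked against.
direct_dft <- function(times, values, window, freq) {
  sel <- times >= window$t1 - 1e-9 & times < window$t2 - 1e-9
  x <- values[sel]
  n <- length(x)
  k <- round((window$t2 - window$t1) * freq)
  w <- exp(-2i * pi * k * (seq_len(n) - 1) / n)
  X <- sum(x * w)
  amp <- if (k == 0) Mod(X) / n else 2 * Mod(X) / n
  list(amplitude = amp, phase_deg = Arg(X) * 180 / pi)
}

# A trace tibble holding one synthetic signal on a uniform grid.
make_trace <- function(values, rate = 1000, t0 = 0, condition = 0) {
  tibble::tibble(
    trial_id = 1L,
    condition = condition,
    time_s = t0 + (seq_along(values) - 1) / rate,
    pupil = values
  )
}

# Default small session for pipeline tests: 250 Hz keeps the integer-cycle
# window grid-aligned while being 4x cheaper than 1 kHz.
small_config <- function(levels = seq(6.04, 36.04, length.out = 9),
                         repeats = 3, fixed = 21.04) {
  session_config(fixed_luminance = fixed, variable_levels = levels,
                 repeats = repeats)
}

quiet_observer <- function(...) observer_model(noise_sd = 0, ...)
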