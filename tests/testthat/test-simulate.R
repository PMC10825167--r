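test_that("the perceived drive is a square wave starting with the fixed colour", {
  cfg <- small_config()
  mod <- quiet_observer(gain = 0.9)
  t <- seq(0, cfg$half_period_s - 1e-3, by = 0.01)
  expect_true(all(perceived_drive(cfg, 30, mod, t) == cfg$fixed_luminance))
  t2 <- t + cfg$half_period_s
  expect_true(all(perceived_drive(cfg, 30, mod, t2) == 0.9 * 30))
  expect_equal(perceived_drive(cfg, 30, mod, -0.2), cfg$fixed_luminance)
  # square-wave mean over one full period
  tt <- seq(0, cfg$period_s, length.out = 2001)[-2001]
  expect_equal(mean(perceived_drive(cfg, 30, mod, tt)),
               (cfg$fixed_luminance + 0.9 * 30) / 2, tolerance = 1e-3)
})

test_that("noiseless equiluminant trials carry no tagged oscillation", {
  cfg <- small_config()
  mod <- quiet_observer(gain = 0.8)
  equi <- cfg$fixed_luminance / 0.8
  tr <- simulate_trial(cfg, equi, mod, seed = 1, rate = 250)
  w <- analysis_window(1.132, cfg$period_s, 4)
  amp <- fft_component(tr, w, cfg$tag_frequency_hz)$amplitude
  expect_lt(amp, 1e-6)
})

test_that("conditions symmetric about the equiluminant point mirror in phase", {
  cfg <- session_config(variable_levels = c(11.04, 21.04, 31.04), repeats = 1)
  mod <- quiet_observer(gain = 1)
  w <- analysis_window(1.132, cfg$period_s, 4)
  lo <- fft_component(simulate_trial(cfg, 11.04, mod, 1, rate = 500), w,
                      cfg$tag_frequency_hz)
  hi <- fft_component(simulate_trial(cfg, 31.04, mod, 1, rate = 500), w,
                      cfg$tag_frequency_hz)
  expect_equal(lo$amplitude, hi$amplitude, tolerance = 1e-6)
  dphi <- abs(pftm:::wrap_degrees(lo$phase_deg - hi$phase_deg))
  expect_equal(dphi, 180, tolerance = 1)
})

test_that("noiseless tag amplitude grows with perceived luminance difference", {
  cfg <- small_config(levels = seq(1.04, 41.04, length.out = 11), repeats = 1)
  mod <- quiet_observer(gain = 0.85)
  w <- analysis_window(1.132, cfg$period_s, 4)
  amp <- vapply(cfg$variable_levels, function(L) {
    fft_component(simulate_trial(cfg, L, mod, 1, rate = 250), w,
                  cfg$tag_frequency_hz)$amplitude
  }, numeric(1))
  d <- abs(0.85 * cfg$variable_levels - cfg$fixed_luminance)
  expect_true(all(diff(amp[order(d)]) >= -1e-9))
})

test_that("noiseless phases take exactly two values 180 degrees apart", {
  cfg <- small_config(levels = seq(6.04, 36.04, length.out = 9), repeats = 1)
  mod <- quiet_observer(gain = 1)
  w <- analysis_window(1.132, cfg$period_s, 4)
  ph <- vapply(cfg$variable_levels[cfg$variable_levels != 21.04], function(L) {
    fft_component(simulate_trial(cfg, L, mod, 1, rate = 250), w,
                  cfg$tag_frequency_hz)$phase_deg
  }, numeric(1))
  below <- ph[cfg$variable_levels[cfg$variable_levels != 21.04] < 21.04]
  above <- ph[cfg$variable_levels[cfg$variable_levels != 21.04] > 21.04]
  expect_lt(max(abs(below - below[1])), 1)
  expect_lt(max(abs(above - above[1])), 1)
  expect_equal(abs(pftm:::wrap_degrees(below[1] - above[1])), 180,
               tolerance = 1)
})

test_that("sessions are reproducible and fully randomised", {
  cfg <- small_config(levels = c(10, 20, 30), repeats = 2)
  mod <- observer_model()
  s1 <- simulate_session(cfg, mod, seed = 42, rate = 100)
  s2 <- simulate_session(cfg, mod, seed = 42, rate = 100)
  expect_identical(s1, s2)
  expect_equal(dplyr::n_distinct(s1$trial_id), 6)
  counts <- dplyr::count(dplyr::distinct(s1, trial_id, condition), condition)
  expect_equal(counts$n, rep(2L, 3))
  s3 <- simulate_session(cfg, mod, seed = 43, rate = 100)
  expect_false(identical(s1$pupil, s3$pupil))
})

test_that("AR(1) noise leaves the expected tag amplitude unbiased", {
  cfg <- session_config(variable_levels = c(11.04, 26.04, 31.04), repeats = 1)
  mod <- observer_model(gain = 1)
  w <- analysis_window(1.132, cfg$period_s, 4)
  f <- cfg$tag_frequency_hz
  clean <- fft_component(
    simulate_trial(cfg, 31.04, quiet_observer(gain = 1), 1, rate = 250), w, f)
  # average the *complex* tagged component over noisy trials: additive noise
  # with no systematic phase must leave it unbiased
  reps <- vapply(1:200, function(i) {
    tr <- simulate_trial(cfg, 31.04, mod, seed = 1000 + i, rate = 250)
    cmp <- fft_component(tr, w, f)
    complex(modulus = cmp$amplitude, argument = cmp$phase_deg * pi / 180)
  }, complex(1))
  avg <- mean(reps)
  expect_equal(Mod(avg), clean$amplitude, tolerance = 0.1)
})

test_that("binomial 2AFC simulation matches its generating Quick observer", {
  tab0 <- simulate_2afc(c(0, 10, 20), 20, 3, n_per_level = 30, seed = 9)
  expect_equal(tab0$n_chose[tab0$level == 0], 0L)  # p = 0 at x = 0
  expect_identical(simulate_2afc(1:5 * 10, 20, 3, seed = 4),
                   simulate_2afc(1:5 * 10, 20, 3, seed = 4))
  big <- simulate_2afc(20, 20, 3, n_per_level = 1000, seed = 11)
  phat <- big$n_chose / big$n_total
  expect_lt(abs(phat - 0.5), 1.96 * sqrt(0.25 / 1000) + 1e-9)
})
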