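test_that("spline minimum localises V-shaped and parabolic tuning curves", {
  levels <- seq(1.6, 33.05, length.out = 21)
  half_step <- diff(levels)[1] / 2
  v <- fit_minimum(levels, abs(levels - 11.04))
  expect_equal(v$min_luminance, 11.04, tolerance = half_step)
  expect_false(v$boundary)

  lv10 <- seq(5, 35, length.out = 10)
  cc <- 22.3
  par <- fit_minimum(lv10, (lv10 - cc)^2 + 0.1)
  expect_equal(par$min_luminance, cc, tolerance = diff(lv10)[1] / 2)

  mono <- fit_minimum(lv10, lv10 * 0.2)
  expect_equal(mono$min_luminance, min(lv10))
  expect_true(mono$boundary)

  expect_error(fit_minimum(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(fit_minimum(lv10, c(NA, rep(1, 9))), "finite")
})

test_that("spline minimum is invariant to amplitude scale", {
  set.seed(5)
  levels <- seq(2, 40, length.out = 12)
  amps <- (levels - 24)^2 / 50 + rexp(12, 10)
  m1 <- fit_minimum(levels, amps)$min_luminance
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(fit_minimum(levels, k * amps)$min_luminance, m1)
  }
})

test_that("phase transitions are located for steps and logistic curves", {
  levels <- seq(15, 30, by = 1)
  step <- ifelse(levels < 22.5, 0, 180)
  pt <- detect_phase_transition(levels, step)
  expect_true(pt$found)
  expect_equal(pt$midpoint, 22.5)
  expect_lte(pt$start, 22.5)
  expect_gte(pt$end, 22.5)

  cc <- 23.7
  logi <- 180 / (1 + exp(-(levels - cc) / 0.8))
  ptl <- detect_phase_transition(levels, logi)
  expect_true(ptl$found)
  expect_equal(ptl$midpoint, cc, tolerance = 0.5)

  flat <- detect_phase_transition(levels, rep(40, length(levels)))
  expect_false(flat$found)
  expect_true(is.na(flat$midpoint))
})

test_that("phase detection unwraps across the -180/180 seam", {
  levels <- seq(10, 30, by = 2)
  # -30 deg plateau flipping to 140 deg, as in a same-colour control session
  ph <- ifelse(levels < 21, -30, 140)
  pt <- detect_phase_transition(levels, ph)
  expect_true(pt$found)
  expect_equal(pt$midpoint, 21, tolerance = 1)
  expect_equal(pt$excursion, 170)
})

test_that("luminance ratios follow fixed / minimum with positivity guards", {
  expect_equal(luminance_ratio(21.72, 21.72), 1)
  expect_equal(luminance_ratio(20, 25), 0.8)
  expect_error(luminance_ratio(20, 0), "> 0")
  expect_error(luminance_ratio(-3, 5), "> 0")
})

test_that("the full estimate combines spline minimum and phase midpoint", {
  cfg <- small_config(levels = seq(6.04, 36.04, length.out = 9), repeats = 1)
  s <- simulate_session(cfg, quiet_observer(gain = 1), seed = 2, rate = 250)
  est <- pftm_analyze(s, cfg)$estimate
  expect_equal(est$ratio, 1, tolerance = 0.02)
  expect_true(est$phase_transition$found)
  expect_true(est$confirmed)
  expect_equal(est$combined_luminance,
               mean(c(est$min_luminance, est$phase_transition$midpoint)))
  # within-range guarantee: no extrapolation beyond the tested levels
  expect_gte(est$min_luminance, min(cfg$variable_levels))
  expect_lte(est$min_luminance, max(cfg$variable_levels))
  td <- tidy(est)
  expect_true(all(c("min_luminance", "ratio", "phase_midpoint") %in% td$term))
  expect_false(glance(est)$boundary)
})

test_that("a known fixed/minimum pair yields the printed ratio", {
  cfg <- small_config(fixed = 20)
  res <- tibble::tibble(
    condition = seq(10, 40, length.out = 8),
    tag_amplitude = abs(seq(10, 40, length.out = 8) - 25),
    tag_phase_deg = ifelse(seq(10, 40, length.out = 8) < 25, 0, 180),
    mean_amplitude = 1, n_trials = 5
  )
  est <- estimate_equiluminance(res, cfg)
  expect_equal(est$ratio, 20 / 25, tolerance = 0.02)
})
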