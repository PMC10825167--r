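test_that("Gaussian smoothing preserves constants, mass, and identity cases", {
  const <- make_trace(rep(5, 500))
  expect_equal(smooth_pupil(const, 30)$pupil, rep(5, 500))
  # discrete convolution conserves the mass of a unit impulse (interior)
  imp <- make_trace(c(rep(0, 250), 1, rep(0, 249)))
  expect_equal(sum(smooth_pupil(imp, 30)$pupil), 1, tolerance = 1e-9)
  expect_equal(smooth_pupil(imp, 0)$pupil, imp$pupil)
  expect_error(smooth_pupil(make_trace(numeric(0))), "empty|two samples")
})

test_that("smoothing attenuates a tag-frequency sinusoid by the kernel transfer gain", {
  rate <- 1000
  f <- 1 / 0.566
  w <- analysis_window(1.132, 0.566, 2)
  tr <- make_trace(cos(2 * pi * f * ((0:3499) / rate)), rate = rate)
  sm <- smooth_pupil(tr, 30)
  k <- pftm:::gaussian_kernel(30, rate)
  tau <- (seq_along(k) - (length(k) + 1) / 2) / rate
  predicted_gain <- sum(k * cos(2 * pi * f * tau))
  measured <- fft_component(sm, w, f)$amplitude
  expect_equal(measured, predicted_gain, tolerance = 1e-3)
})

test_that("baseline correction subtracts the windowed mean", {
  flat <- make_trace(rep(3.2, 400), rate = 1000, t0 = -0.2)
  expect_equal(baseline_correct(flat, "prestim")$pupil, rep(0, 400))
  # window_mean mode zeroes the mean over the FFT window by construction
  w <- analysis_window(0.05, 0.05, 2)
  tr <- make_trace(5 + cumsum(rnorm(400, 0, 0.01)), rate = 1000, t0 = -0.2)
  bc <- baseline_correct(tr, "window_mean", w)
  sel <- bc$time_s >= w$t1 - 1e-9 & bc$time_s <= w$t2 + 1e-9
  expect_equal(mean(bc$pupil[sel]), 0, tolerance = 1e-9)
  expect_error(baseline_correct(tr, "window_mean", c(10, 11)), "no samples")
})

test_that("trial averaging gives pointwise mean and SEM and rejects mixed grids", {
  t1 <- make_trace(rep(1, 100), condition = 5)
  t3 <- make_trace(rep(3, 100), condition = 5) |> dplyr::mutate(trial_id = 2L)
  avg <- average_trials(dplyr::bind_rows(t1, t3))
  expect_equal(unique(avg$mean), 2)
  expect_equal(unique(avg$sem), 1)  # SD = sqrt(2), / sqrt(2)
  expect_equal(unique(avg$n), 2L)
  same <- average_trials(dplyr::bind_rows(
    t1, dplyr::mutate(t1, trial_id = 2L)))
  expect_equal(same$mean, t1$pupil)
  expect_equal(unique(same$sem), 0)
  mixed <- dplyr::bind_rows(
    t1, make_trace(rep(1, 50), rate = 500, condition = 5) |>
      dplyr::mutate(trial_id = 2L))
  expect_error(average_trials(mixed), "common time grid")
})

test_that("trial averaging is permutation-invariant", {
  set.seed(9)
  trials <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_trace(rnorm(80), condition = 7) |> dplyr::mutate(trial_id = i)
  }))
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(average_trials(trials), average_trials(shuffled))
})

test_that("downsampling requires an integer factor and preserves constants", {
  tr <- make_trace(rep(2.5, 1000))
  expect_error(downsample(tr, 300), "not an integer multiple")
  down <- downsample(tr, 125)
  expect_equal(down$pupil, rep(2.5, nrow(down)))
  expect_equal(pftm:::trace_rate(down$time_s), 125)
  expect_error(downsample(tr, 2000), "exceeds")
})

test_that("decimation to ~120 Hz leaves the tagging amplitude intact", {
  # slow tagged oscillations survive heavy decimation: the analysis is
  # eye-tracker-rate independent
  f <- 1 / 0.566
  w <- analysis_window(0.566, 0.566, 4)
  for (rates in list(c(1000, 125), c(960, 120))) {
    rate <- rates[1]
    n <- round(3.5 * rate)
    tr <- make_trace(5 + 0.3 * cos(2 * pi * f * (0:(n - 1)) / rate), rate = rate)
    a0 <- fft_component(tr, w, f)$amplitude
    a1 <- fft_component(downsample(tr, rates[2]), w, f)$amplitude
    expect_equal(a1, a0, tolerance = 0.02)
  }
})
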