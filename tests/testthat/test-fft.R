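test_that("analysis window is an exact integer multiple of the period", {
  w <- analysis_window(0.3, 0.567, 4)
  expect_identical(w$t2, 0.3 + 0.567 * 4)
  expect_equal(w$t2, 2.568)
  expect_equal(analysis_window(1.0, 0.567, 1)$t2, 1.567)
  expect_error(analysis_window(0.3, 0.567, 0), "integer >= 1")
  expect_error(analysis_window(0.3, -0.5, 2), "> 0")
})

test_that("single-bin DFT recovers amplitude and phase of on-bin cosines", {
  rate <- 1000
  w <- analysis_window(0.3, 0.566, 4)
  f <- 1 / 0.566
  t <- (0:3499) / rate
  cosine <- make_trace(0.5 * cos(2 * pi * f * (t - 0.3)), rate = rate)
  got <- fft_component(cosine, w, f)
  expect_equal(got$amplitude, 0.5, tolerance = 1e-3)
  expect_equal(got$phase_deg, 0, tolerance = 0.2)
  neg <- make_trace(-0.5 * cos(2 * pi * f * (t - 0.3)), rate = rate)
  gneg <- fft_component(neg, w, f)
  expect_equal(gneg$amplitude, 0.5, tolerance = 1e-3)
  expect_equal(abs(gneg$phase_deg), 180, tolerance = 0.2)
  const <- make_trace(rep(4, 3500), rate = rate)
  expect_equal(fft_component(const, w, f)$amplitude, 0, tolerance = 1e-12)
  expect_equal(fft_component(const, w, 0)$amplitude, 4)
  # off-bin frequencies and windows beyond the trace are contract errors
  expect_error(fft_component(cosine, w, 1.5), "off the DFT grid")
  expect_error(fft_component(cosine, analysis_window(3, 0.566, 4), f),
               "exceeds the trace")
})

test_that("fft-based extraction agrees with a direct DFT sum", {
  set.seed(101)
  rate <- 500
  w <- analysis_window(0.2, 0.5, 3)
  for (i in 1:10) {
    tr <- make_trace(rnorm(1500, 5, 1), rate = rate)
    for (f in c(0, 2, 6)) {
      got <- fft_component(tr, w, f)
      ref <- direct_dft(tr$time_s, tr$pupil, w, f)
      expect_equal(got$amplitude, ref$amplitude, tolerance = 1e-9)
      if (f > 0) {
        expect_equal(got$phase_deg, pftm:::wrap_degrees(ref$phase_deg),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("spectra are linear in on-bin components and satisfy Parseval", {
  rate <- 200
  w <- analysis_window(0, 1, 2)  # 2 s window, 0.5 Hz bins
  t <- (0:399) / rate
  x <- 0.7 * cos(2 * pi * 3 * t + 0.4) + 0.2 * cos(2 * pi * 8.5 * t)
  sp <- spectrum(make_trace(x, rate = rate), w, fmax = 20)
  expect_equal(sp$freq[1], 0)
  expect_equal(diff(sp$freq), rep(0.5, nrow(sp) - 1), tolerance = 1e-9)
  expect_equal(sp$amplitude[sp$freq == 3], 0.7, tolerance = 1e-9)
  expect_equal(sp$amplitude[sp$freq == 8.5], 0.2, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[!sp$freq %in% c(3, 8.5)]), 1e-9)
  # energy identity for the single-sided scaling
  expect_equal(sum(sp$amplitude[sp$freq > 0]^2) / 2,
               mean((x - mean(x))^2), tolerance = 1e-6)
  zero <- spectrum(make_trace(rep(0, 400), rate = rate), w, fmax = 20)
  expect_true(all(zero$amplitude == 0))
  expect_error(spectrum(make_trace(x, rate = rate), w, fmax = 300), "Nyquist")
})

test_that("the tagging frequency lands exactly on bin rho of its own window", {
  for (rho in c(1, 3, 5)) {
    per <- 0.566
    w <- analysis_window(0, per, rho)
    expect_identical(round((w$t2 - w$t1) * (1 / per)), as.numeric(rho))
  }
})

test_that("amplitude at positive bins ignores constant offsets", {
  rate <- 400
  w <- analysis_window(0.25, 0.5, 2)
  t <- (0:799) / rate
  x <- 0.3 * sin(2 * pi * 4 * t)
  a0 <- fft_component(make_trace(x, rate = rate), w, 4)$amplitude
  a1 <- fft_component(make_trace(x + 17.3, rate = rate), w, 4)$amplitude
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("tag_table extracts per-condition mean and tag components", {
  cfg <- small_config(levels = seq(11.04, 31.04, length.out = 5), repeats = 1)
  mod <- quiet_observer(gain = 1)
  s <- simulate_session(cfg, mod, seed = 3, rate = 250)
  avg <- average_trials(s)
  w <- analysis_window(1.132, cfg$period_s, 4)
  tab <- tag_table(avg, cfg, w)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$tag_amplitude >= 0))
  expect_true(all(tab$mean_amplitude >= 0))
  expect_true(all(tab$tag_phase_deg > -180 & tab$tag_phase_deg <= 180))
  # the equiluminant condition (gain 1: level == fixed) has the smallest
  # oscillation of all conditions
  expect_equal(tab$condition[which.min(tab$tag_amplitude)], 21.04)
  single <- tag_table(dplyr::filter(avg, condition == 11.04), cfg, w)
  expect_equal(nrow(single), 1)
})

test_that("amplitude normalisation maps the largest to one and keeps the argmax", {
  res <- tibble::tibble(tag_amplitude = c(3, 6, 1.5))
  norm <- normalise_amplitudes(res)
  expect_equal(norm$norm_amplitude, c(0.5, 1, 0.25))
  expect_equal(which.max(norm$norm_amplitude), which.max(res$tag_amplitude))
  expect_error(normalise_amplitudes(tibble::tibble(tag_amplitude = c(0, 0))),
               "all amplitudes are zero")
})
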