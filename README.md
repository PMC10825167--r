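# pftm — pupil frequency-tagging for chromatic equiluminance

Two colours are *equiluminant* for an observer when their perceived
luminances match, so that exchanging them produces no response in the
luminance pathway. Because the luminance response to a given physical
luminance (cd/m²) varies substantially between individuals, experiments on
colour perception must calibrate stimuli per observer — and the classical
psychophysical calibrations (heterochromatic minimum flicker,
minimum-motion nulling) require instructed, cooperative observers, which
rules out infants and animal subjects.

`pftm` implements an objective alternative based on the pupillary light
reflex. A disc alternates between a fixed colour (e.g. red at luminance
L_f) and a variable colour (e.g. green at L_v) every 0.283 s — a tagging
frequency of f = 1/(2 × 0.283) ≈ 1.77 Hz, slow enough to drive the pupil,
fast enough to avoid melanopsin dynamics. The pupil then oscillates at f
with amplitude proportional to the perceived luminance difference
|g·L_v − L_f|, where g is the observer's perceptual gain for the variable
colour. Scanning L_v and reading the single-sided FFT amplitude A(f) at the
tagged bin yields a V-shaped tuning curve whose minimum L* is the
observer's equiluminance point; the oscillation phase flips by ~180° across
L*, which independently confirms it. The setting is reported as the ratio
L_f / L*.

The package provides, as tidyverse-style functions over tibbles:

* stimulus-locked preprocessing: Gaussian smoothing, pre-stimulus or
  window-mean baseline correction, per-condition trial averaging,
  integer-factor downsampling;
* single-bin DFT amplitude/phase over integer-cycle windows
  (`analysis_window()`, `fft_component()`, `spectrum()`, `tag_table()`);
* the equiluminance estimator: generalized-cross-validated smoothing-spline
  minimum plus phase-transition detection (`fit_minimum()`,
  `detect_phase_transition()`, `estimate_equiluminance()`, or end-to-end
  `pftm_analyze()`);
* companion psychophysics: Quick-function maximum-likelihood fits to 2AFC
  minimum-motion data (`fit_quick_mle()`, `pse()`) and minimum-flicker
  aggregation (`flicker_summary()`);
* method-agreement statistics: one-tailed Pearson/Spearman with Fisher-z
  effect sizes, Bland–Altman limits of agreement (`correlate_methods()`,
  `bland_altman()`, `summarise_ratios()`);
* a synthetic pupil-session simulator with known ground truth
  (`observer_model()`, `simulate_session()`, `simulate_2afc()`), used
  throughout the test suite for parameter-recovery checks;
* `autoplot()`/`plot_*()` ggplot2 diagnostics and broom-style
  `tidy()`/`glance()` methods.

## Worked example

Simulate an observer whose perceptual gain for green is 0.85 (true
equiluminant green: 21.04 / 0.85 = 24.75 cd/m²), then run the full
analysis:

```r
library(pftm)

cfg <- session_config(
  fixed_colour = "red", fixed_luminance = 21.04, variable_colour = "green",
  variable_levels = seq(4.58, 41.24, length.out = 10), repeats = 5
)
obs     <- observer_model(gain = 0.85)
samples <- simulate_session(cfg, obs, seed = 42)
fit     <- pftm_analyze(samples, cfg)
fit
#> <pftm analysis> 10 conditions, window [1.132, 3.396] s (4 cycles)
#> <equiluminance estimate>
#>   amplitude minimum: 24.38 cd/m^2 (raw argmin 24.95)
#>   fixed : variable ratio: 0.863
#>   phase transition: 20.87 -> 29.02 cd/m^2 (midpoint 25.38), confirmed by phase (tol 4.07)
#>   combined (amplitude+phase) estimate: 24.88 cd/m^2 (ratio 0.846)
```

The spline minimum (24.38 cd/m²) recovers the simulated equiluminant point
to within half a luminance step at five repeats per level, the red:green
ratio 0.863 approximates the generating gain 0.85, and the phase-transition
midpoint falls within one step of the amplitude minimum, confirming it.
Averaging the two landmarks gives the combined estimate (ratio 0.846).
`fit$results` holds the per-condition table (`condition`, `mean_amplitude`,
`tag_amplitude`, `tag_phase_deg`, `n_trials`); `autoplot(fit)` draws the
tuning-and-phase figure.

The companion estimators follow the same pattern:

```r
tab <- simulate_2afc(seq(10, 40, length.out = 9), alpha = 24.75, beta = 4,
                     n_per_level = 10, seed = 42)
pse(fit_quick_mle(tab))             # 23.2 cd/m^2 -> ratio 21.04/23.2 = 0.91
flicker_summary(c(24.1, 25.3, 24.8, 26.0, 25.1), 21.04)
#>   mean_ratio sd_ratio     n
#> 1      0.840   0.0234     5
```

and the agreement statistics run over a long participant × method table:

```r
correlate_methods(pftm_example_ratios("wide"), flicker, pftm)
#> r = 0.727, Fisher z = 0.922, one-tailed p = 0.021 (n = 8)
bland_altman(pftm_example_ratios("wide"), motion, pftm)
#> mean difference -0.04, limits of agreement [-0.20, 0.12]
```

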