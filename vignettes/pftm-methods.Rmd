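---
title: "Estimating chromatic equiluminance from tagged pupil oscillations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chromatic equiluminance from tagged pupil oscillations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pftm)
```

## The measurement model

A disc alternates between a fixed colour at luminance $L_f$ and a variable
colour at $L_v$, each shown for one half-period $h$ (default $h = 0.283$ s,
34 frames at 120 Hz), so the exchange is tagged at
$f = 1/(2h) \approx 1.77$ Hz. Pupil diameter tracks *perceived* luminance:
writing $g$ for the observer's perceptual gain on the variable colour, the
luminance signal reaching the pupillomotor pathway is a square wave
alternating between $L_f$ and $g L_v$. Its fundamental component has
amplitude proportional to $|g L_v - L_f|$, so the pupil oscillates at $f$
with an amplitude that vanishes at the observer's equiluminance point
$L^* = L_f / g$ and a phase that reverses by $180^\circ$ as $L_v$ crosses
$L^*$ (the darker-than-fixed and lighter-than-fixed drives are sign
flips of each other). The analysis assumes:

* pupil diameter responds (sluggishly, with a lag of roughly half a
  second) but *linearly enough* to the slow luminance modulation that the
  amplitude at the tagged bin is monotone in $|g L_v - L_f|$ on each side
  of the minimum — nothing stronger, because the estimator only locates the
  minimum;
* fixation is maintained, so the retinal stimulus is stationary over a
  trial;
* trials are long enough to contain an integer number of tagging periods
  after the onset transient.

The estimate is reported as the ratio $L_f / L^*$ (e.g. red : green).

## The pipeline and its parameters

`pftm_analyze()` chains the stages below; every stage is exported and
individually testable.

**Smoothing** (`smooth_pupil()`, default `window_ms = 30`). A truncated
Gaussian of total width 30 ms (a light pre-filter at 1 kHz sampling). The
kernel uses $\sigma = \mathrm{window}/5$, truncation at
$\pm\mathrm{window}/2$, renormalised to unit sum; at trace edges the
window shrinks to the available samples and renormalises, so constants are
preserved everywhere. At 1.77 Hz the kernel's transfer gain is
$\approx 0.9999$, so the tagged amplitude is essentially untouched — the
tests assert the measured attenuation matches the kernel transfer function
to $10^{-3}$.

**Baseline correction** (`baseline_correct()`). Two conventions, both
subtracting a per-trial scalar: `"prestim"` (mean over $-0.1$ to $+0.1$ s
around onset; $\pm 0.2$ s is conventional for non-human primate sessions,
both are parameters) keeps the stimulus-driven baseline offset visible at
0 Hz; `"window_mean"` (mean over the FFT window, the default) zeroes the
0 Hz bin by construction and gives slightly better signal-to-noise at the
tagged bin. The choice does not affect the tagged bin itself, which is
blind to constants.

**Averaging** (`average_trials()`). Pointwise mean and SEM
($\mathrm{SD}/\sqrt{n}$) across a condition's repeats after smoothing and
baseline correction. Mismatched time grids are an error — no silent
resampling.

**Windowing** (`analysis_window(t1, period_s, cycles)`). The FFT window
must span an integer number $\rho$ of tagging periods,
$t_2 = t_1 + \rho \cdot \mathrm{period}$, which places the tagging
frequency exactly on DFT bin $\rho$: with a rectangular window there is
then no leakage at that bin, so no taper is applied. The default $t_1$ is
the first colour-reversal boundary at or after 1 s post-onset (the onset
transient of the pupil response is excluded, and starting at a reversal
boundary makes phases comparable across sessions); it is user-overridable,
and analyses that need five cycles inside a 3.5 s trial can start at
0.566 s instead. The default $\rho$ is the largest count that fits before
the trial ends.

**Spectral readout** (`fft_component()`). Single-sided scaling: amplitude
$2|X_k|/N$ for $k>0$ and $|X_0|/N$ at 0 Hz, so a pure sinusoid of
amplitude $A$ reads $A$ and the 0 Hz bin is the absolute window mean.
Phase uses the cosine convention referenced to the window start, wrapped
to $(-180^\circ, 180^\circ]$. $N$ counts samples in the half-open
$[t_1, t_2)$, which keeps $N = \rho \cdot \mathrm{period} \cdot
\mathrm{rate}$ exact on aligned grids. Off-bin frequencies (bin index not
integer within $10^{-6}$) are contract errors, not silently rounded. The
implementation is `stats::fft()`; the tests check it against an
independent direct DFT sum at $10^{-9}$ relative tolerance.

**Minimum estimation** (`fit_minimum()`). A cubic smoothing spline
(`stats::smooth.spline`) with its smoothing parameter chosen by
generalized cross-validation — an automatic fit with no per-session
tuning — evaluated on a 1001-point grid restricted to the tested luminance
range; the reported minimum never extrapolates. Requires at least four
distinct levels. A minimum on the range boundary is reported but flagged
`boundary = TRUE` ("unbracketed"): a ratio from an edge means the level
range should be re-centred and re-run. The raw per-condition argmin is
reported alongside, since with few levels the spline minimum and the raw
minimum can disagree noticeably; the spline is the primary estimate
because it interpolates between levels.

**Phase confirmation** (`detect_phase_transition()`). Phases are unwrapped
over sorted levels (adjacent jumps folded within $\pm 180^\circ$). The low
and high plateaus are medians over the first and last quartile of levels —
medians because a single noisy endpoint should not drag a plateau. The
transition midpoint is the level at which the unwrapped phase crosses the
plateau mean, interpolated linearly between the bracketing levels; the
transition start/end are the outermost levels still within $20^\circ$ of
their plateau. A total excursion under $90^\circ$ is declared "no
transition" rather than guessed — half of the ideal $180^\circ$ flip, below
which a midpoint is not meaningful. The estimate is `confirmed` when the
spline minimum and phase midpoint agree within `phase_tolerance` (default:
one luminance step, the resolution at which the two landmarks can be
expected to agree).

**Combined estimate.** When both landmarks exist, their unweighted mean is
reported as `combined_luminance`. A variance-weighted combination would
need noise estimates for both landmarks that a single session does not
provide; the unweighted mean is the transparent default.

## Calibration

Video eye trackers report pupil size in arbitrary (area) units. Recording
an artificial pupil of known diameter $d$ (8 mm by default) gives
$\theta = d / \sqrt{\mathrm{units}}$, and samples convert as
$\mathrm{diameter} = \theta \sqrt{\mathrm{data}}$ (`calibration_factor()`,
`apply_calibration()`). Calibration is optional: every stage of the
estimator is invariant to a common positive scale (asserted as a property
test), so sessions analysed in arbitrary units give the same ratio.

## Downsampling

`downsample()` implements integer-factor decimation with a centred
moving-average anti-alias filter. The decimation factor must be an exact
integer — rational resampling is out of scope, so a 1000 Hz recording
drops to 125 or 250 Hz, and a 960 Hz recording to 120 Hz. The tests
confirm that the tagged amplitude survives decimation to ~120 Hz within
2%, i.e. the method does not depend on high-rate eye trackers.

## The Quick-function estimators

Minimum-motion 2AFC data (level, rightward choices, trials) are fitted
with the Quick form
$$P(x) = \gamma + (1 - \gamma - \lambda)\left(1 - 2^{-(x/\alpha)^\beta}\right),$$
by maximising the binomial log-likelihood in $(\log\alpha, \log\beta)$
with `stats::optim` (L-BFGS-B), multi-started from a log-spaced
$\alpha$ grid crossed with $\beta \in \{1, 2, 4, 8\}$ to avoid local
optima. One printed variant of this function subtracts the $2^{-(\cdot)}$
term instead of multiplying the bracket; that form cannot pass through
50% at $\alpha$, so the standard multiplicative form above is
implemented. For the direction task the response is coded as proportion
rightward on a 0–1 axis with $\gamma = \lambda = 0$ fixed (a 50% lower
asymptote would make the 50% PSE meaningless); $\beta$ is left free since
fixing it is an unverifiable assumption. The likelihood is written as the
explicit cross-entropy (the binomial coefficient dropped), which also
accepts expected — non-integer — counts; refitting a fitted curve's own
expected counts reproduces $(\alpha, \beta)$ to $10^{-3}$, a fixed-point
check in the tests. The PSE has the closed form
$\alpha(-\log_2(1-q))^{1/\beta}$ with
$q = (0.5-\gamma)/(1-\gamma-\lambda)$, reducing to $\alpha$ for symmetric
asymptotes. Degenerate data are handled explicitly: all-identical
responses are an error (PSE unidentifiable); perfectly separable data are
fitted but flagged `separable`/`boundary` with the slope capped at 64.

Minimum-flicker matching needs no fitting: each repeat yields one matched
luminance, summarised as mean and SD of fixed/match ratios.

## Agreement statistics

`correlate_methods()` computes Pearson's $r$ or Spearman's $\rho$ (Pearson
correlation of midranks), the Fisher $z = \operatorname{arctanh}(r)$
effect size, and a one-tailed p-value from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df — one-tailed because the
directional hypothesis is positive agreement between methods measuring
the same quantity. The t approximation is used for both coefficients.
Correlations within $10^{-12}$ of $\pm 1$ are snapped to $\pm 1$ and
report an infinite $z$. `bland_altman()` takes differences as second −
first, limits at mean $\pm 1.96\,\mathrm{SD}$ ($n-1$ SD), with 95% CIs
$\mathrm{mean} \pm t_{0.975,n-1}\mathrm{SD}/\sqrt{n}$ for the mean and
$\mathrm{limit} \pm t_{0.975,n-1}\mathrm{SD}\sqrt{3/n}$ for the limits.
The bundled `pftm_example_ratios()` table (eight observers × three
methods) is the worked input for all of these.

## The synthetic observer

`observer_model()` + `simulate_session()` generate sessions with known
ground truth. The deterministic part convolves the perceived-luminance
difference from background with a causal gamma-density impulse response
(shape 8, scale set so the kernel peaks at 0.45 s) and delays it by a
0.2 s latency — together these reproduce the ~0.5–0.7 s apparent onset and
the sluggish, low-pass oscillation seen in real recordings. Higher
perceived luminance constricts (diameter decreases). The mean and
oscillatory drive components carry separate gains (`k_dc = 0.01`,
`k_osc = 0.02` mm per cd/m²), because the baseline offset and the
oscillation are distinct empirical features. AR(1) Gaussian noise
(stationary SD 0.02 mm, lag-one correlation 0.97 at 1 kHz) emulates slow
physiological drift; its spectrum is red, concentrating power away from
the tagged bin, like real pupil noise. Defaults produce tagged amplitudes
of roughly 0.01–0.04 mm over a typical level range — the same order as the
noise floor per trial, so recovery genuinely requires the averaging and
integer-cycle windowing machinery.

Per-trial seeds derive from the master seed by one `sample.int()` draw
after `set.seed(master)`, making sessions bit-reproducible.

What the simulator does *not* emulate: blinks and gaze loss, saccadic
artefacts, melanopsin/ipRGC dynamics, attention- or arousal-driven pupil
changes, and any nonlinearity of the pupillary response. Passing recovery
tests therefore demonstrate that the estimator inverts its own generative
assumptions at realistic noise — they do not validate those assumptions
against real eyes. Blink handling in `read_samples()` is deliberately
minimal (gaps are contract violations), since artefact policies are
lab-specific.

## Problem sizes and recovery results

The test suite and `scripts/acceptance.R` run, at full scale:

* same-colour control sessions (fixed green 11.04 cd/m², 21 levels
  1.6–33.05, 10 repeats, 1 kHz): median $|$ratio$ - 1| < 0.02$ over 20
  seeds;
* gain-0.85 sessions (fixed red 21.04, 15 levels centred on the fixed
  value, 10 repeats): median recovered ratio within $\pm 0.03$ of 0.85
  over 20 seeds;
* one-cycle vs five-cycle analysis of identical 20-repeat sessions
  (fixed red 20.34, 15 levels): median ratio change under 0.02 — the
  fixation-length / noise trade-off leaves the estimate stable;
* Quick threshold recovery within 5% at 9 levels × 50 trials.

These sizes mirror the session designs the method is intended for; smaller
configurations (250–500 Hz, 1–3 repeats) are used in unit tests where only
contracts, not statistical power, are at stake.

## Known limitations

* The estimator assumes the minimum is bracketed by the tested levels; a
  boundary minimum is flagged, not resolved.
* The phase-transition detector assumes a single monotone transition;
  multi-modal phase curves (e.g. from fixation loss on a subset of
  conditions) will produce a midpoint between the outermost plateaus.
* GCV can oversmooth very flat tuning curves near threshold-level noise;
  the raw argmin is reported alongside as a cross-check.
* Spearman p-values use the t approximation throughout; exact permutation
  p-values for small n are out of scope.
* Period conventions: the stimulus timing gives a period of
  2 × 0.283 = 0.566 s, while worked windowing arithmetic elsewhere uses
  0.567 s; `analysis_window()` takes the period as a free argument, so
  both are representable, and `session_config()` always derives its own
  period from the half-period.
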