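---
title: "Methods: short-term HRV analysis and trial simulation with hrvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term HRV analysis and trial simulation with hrvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvkit)
```

## Scope and model of the data

hrvkit analyzes short-term (nominally 20-minute) resting heart rate
variability from beat-annotated event series: each detected heartbeat has a
time stamp at 1 ms resolution and a label — `N` (normal sinus), `V`
(ventricular ectopic), `S` (supraventricular ectopic) or `U` (unknown).
R-peak detection itself is upstream hardware/software and out of scope; the
package starts where a beat list exists, and also accepts bare RR-interval
text files (one ms value per line, assumed all-sinus).

The pipeline is the classic clinical-autonomic one:

1. **Editing.** An interval between consecutive beats enters the
   normal-to-normal (NN) series only if both bounding beats are labeled `N`.
   This simultaneously removes intervals that end at an abnormal beat and
   intervals that succeed an ectopic beat (the post-extrasystolic interval,
   which is physiologically disturbed).  Removed intervals are *never*
   interpolated; the NN series carries per-interval contiguity flags so that
   downstream statistics know where gaps are.
2. **Moving-window filtering.** For every set of five contiguous NN
   intervals, a local average of the four neighbors (excluding the center)
   is computed; a central interval more than 20% above or below that average
   is replaced by it.  One left-to-right pass is made and all comparisons use
   the original values, so a replacement never cascades into the next
   window's average.  Exactly 20% deviation is not an outlier (the bound is
   closed), and windows never span a contiguity gap.  Runs shorter than five
   intervals pass through unfiltered; the package is silent about them apart
   from the replacement count attribute.
3. **Quality gate.** Only recordings with strictly more than 95% sinus beats
   are analyzed; a recording at exactly 95% fails.  The strict reading is
   deliberate and conservative — the gate's job is to keep heavily ectopic
   recordings out of spectral and non-linear analysis, where editing gaps
   bias results.
4. **Metric panels** (below).

## Time-domain and geometric panel

`time_domain_metrics()` computes SDNN, SDANN, SDNNi, RMSSD, NNx, pNNx, mean
HR and SD HR.  Conventions that matter:

* All SDs are **population** SDs (`ddof = 0`, configurable).  At n ≈ 1200
  intervals the distinction is negligible, but it makes closed-form test
  oracles exact.
* Successive-difference statistics (RMSSD, NNx, pNNx) use **contiguous
  interval pairs only**: a difference across an editing gap is not a real
  beat-to-beat difference.
* SDANN/SDNNi segment the recording into 5-minute blocks aligned to the
  recording start; an interval belongs to the segment containing its
  terminating beat, and a trailing partial segment is kept only if it spans
  at least 60 s.  With fewer than two segments SDANN is reported missing,
  not zero.
* The `x` in NNx/pNNx defaults to 50 ms (the classical NN50/pNN50) and is
  exposed as a parameter.

`geometric_metrics()` bins the NN histogram at 1/128 s = 7.8125 ms (the
conventional width, aligned to multiples of the width).  The triangular
index is the total count over the modal bin height (1 for a degenerate
single-bin histogram).  TINN fixes the triangle apex at the modal bin's
center and height and least-squares fits the baseline endpoints `N ≤ mode ≤
M` over bin edges; since the left and right residuals are additive, each
side is optimized independently.  The degenerate histogram yields TINN equal
to one bin width.

## Frequency-domain panel

The NN series is cubic-spline interpolated (`resample_nn()`) onto a uniform
4 Hz grid — comfortably above twice the 0.40 Hz analysis edge — and must
span at least 120 s.  `welch_psd()` then averages modified periodograms:
256 s segments, 50% overlap, per-segment linear detrend, Hann window, with
the one-sided density normalized by the window power so that its integral
over frequency equals the time-domain variance (Parseval).  The tests
verify this calibration two ways: white-noise variance recovery within 5%,
and a pure 0.1 Hz, 50 ms sinusoid integrating to A²/2 = 1250 ms² in the LF
band.

`band_powers()` integrates VLF [0.0033, 0.04), LF [0.04, 0.15) and HF
[0.15, 0.40] Hz with half-open edges so no bin is counted twice; total
power is defined as their sum.  Normalized powers are nLF = LF/(LF+HF) and
nHF = HF/(LF+HF) — exact complements by construction — and the
sympathovagal balance is LF/HF (reported missing, not infinite, when HF is
zero).  Peak frequencies are the density argmax within each band; because
the VLF band reaches nearly to DC, peakVLF is typically ≈ 0 on detrended
data.  The Welch segmentation and interpolation settings are conventional
short-term-HRV defaults and all live in `hrv_config()`; none is hard-coded
elsewhere.

## Non-linear panel

* **Poincaré SD1/SD2** (`poincare()`): population SDs of
  `(x_{i+1} − x_i)/√2` and `(x_{i+1} + x_i)/√2` over contiguous pairs.  Two
  identities are enforced by tests: SD1 equals RMSSD/√2 whenever the mean
  successive difference is zero, and SD1² + SD2² equals the sum of the two
  coordinate variances of the return map.
* **Sample entropy** (`sample_entropy()`): −ln(A/B) with template length
  m = 2, Chebyshev distance, tolerance r = 0.2 × SD, self-matches excluded —
  the universal defaults.  Zero match counts yield `NA` with a message,
  never ±Inf.  The implementation is a vectorized O(n²) count verified
  match-for-match against a brute-force double loop.
* **DFA** (`dfa()`): the mean-centered series is integrated; for each box
  size the profile is split into ⌊N/n⌋ non-overlapping boxes (tail beats
  discarded), linearly detrended per box, and F(n) is the RMS residual.
  α1 is the log–log slope over boxes 4–11 (the conventional short range,
  with 4 the minimum for a meaningful linear detrend), α2 over 12–64.
  α1 requires ≥ 100 intervals and α2 ≥ 300; estimates are exactly invariant
  to adding a constant to all intervals.

A finite-size property of DFA worth knowing: for white noise the expected
squared fluctuation is E[F²(n)] = σ²(n² − 4)/(15n), so the slope over boxes
4–11 is ≈ 0.617 rather than the asymptotic 0.5 — the well-documented
small-scale bias of linearly detrended DFA.  The long-range exponent α2
measures ≈ 0.49 on the same input, and Brownian profiles give α1 ≈ 1.5 as
theory predicts.  hrvkit reports the estimator's actual value and does not
attempt bias correction, matching standard practice; comparisons should
therefore always be like-for-like in box range.

Gaps are handled pragmatically in this panel: Poincaré excludes pairs that
straddle a gap, while SampEn and DFA run on the concatenated interval list.
After the 95% sinus gate, gaps are rare, and the concatenation error is far
below sampling variability; this is a documented limitation rather than a
modeling claim.

## Synthetic recordings

`generate_rr_series()` works in the interval (tachogram) domain: the i-th
interval is

    RR_i = mean_rr + lf_amp·sin(2π·lf_freq·t_i + φ_LF)
                   + hf_amp·sin(2π·hf_freq·t_i + φ_HF) + ε_i

with `t_i` the cumulative time at the interval's start and ε white
Gaussian.  Modulation frequencies default to 0.1 Hz (within the LF band)
and 0.25 Hz (respiratory, within HF); an integral-pulse-frequency model was
deliberately avoided because the pipeline consumes intervals, not ECG
waveforms, and the tachogram-domain model makes band-power recovery exactly
checkable (a sinusoid of amplitude A contributes A²/2 ms² to its band).
Beat times are quantized to 1 ms after accumulation so rounding errors do
not build up.  Parameter sets whose amplitudes could produce non-positive
intervals are rejected outright.

`inject_ectopy()` relabels a rounded fraction of beats as `V`/`S`
(positions uniform without replacement, sparing the first and last two
beats so edit windows are well defined) and advances each `V` beat by half
its local RR by default, holding the next beat fixed — a full compensatory
pause.  Beat count and time ordering are invariants.

`generate_cohort()` simulates the three-arm pre/post trial: 30/29/30
completers in land-exercise, water-exercise and control arms with per-arm
age distributions (62.4 ± 7.6, 56.7 ± 8.4, 60.6 ± 8.3 years).  Base
parameters (mean RR 1000 ms, LF amplitude 25 ms, HF amplitude 15 ms, noise
15 ms over 1200 s) were chosen once to place the metric panels in the range
reported for post-event cardiac patients at rest — SDNN in the tens of ms,
LF/HF around 2, SampEn around 2, α1 around 1.1 — and are not tuned per
analysis.  Subjects carry log-normal random effects (σ = 0.2 on amplitudes,
σ = 0.06 on mean RR) shared between visits; visits differ in modulation
phase and noise stream.  The water arm's post-visit multipliers (LF × 1.3,
HF × 0.8, mean RR × 0.94) raise the LF/HF balance, α1 and heart rate —
the directions reported for aquatic training — while land and control
default to no systematic change.

What the generator does *not* emulate: slow non-stationary drifts (so SDANN
is near zero on synthetic data, unlike real recordings), respiratory
frequency wander, circadian structure, and realistic ectopy morphology.
Passing tests therefore demonstrate the correctness of the computations and
the recoverability of known spectral/fractal structure — not clinical
validity on patient data.

## Trial statistics

`within_group_change()` tests pre→post differences per arm: Shapiro–Wilk at
α = 0.05 on the paired differences selects the paired t-test or the
Wilcoxon signed-rank test (normal-approximation p, ties allowed); all-zero
differences return p = 1 by convention.  `ancova_end_of_study()` fits
`post ~ arm + age + baseline` per metric, reports the partial-F omnibus p
for the arm term, and computes the three pairwise arm contrasts from the
coefficient covariance, adjusting with the Sidak formula
p' = 1 − (1 − p)³.  Both the omnibus p (against `car::Anova`) and the
adjusted contrasts (against `emmeans`) are verified to high precision in
the tests.  Missing metric values are dropped listwise per metric with a
message.  Summaries follow the mean (SD) / median (Q1–Q3) convention with
the same normality gate; quartiles use linear interpolation (type 7) and
SDs in summaries are sample SDs, as conventional in cohort tables.

`power_simulation()` measures the operating characteristics of this ANCOVA
by simulation: three arms, standard-normal baselines, one arm shifted by a
stated number of end-of-study SDs.  At the null it reproduces the nominal
5% type-I rate.  At the often-quoted design point "26 per group to detect a
1 SD difference at two-sided α = 0.05 with 80% power", the simulated power
is in fact ≈ 0.95–0.96 (and `power.t.test(n = 26, delta = 1)` gives 0.94):
a 1 SD difference needs only ~17 per group for 80% power, so that design
point is conservative by a wide margin.  The function reports the simulated
truth rather than the textbook target.

## Numerical and design choices, briefly

* Population SDs everywhere in metric panels (configurable); sample SDs in
  cohort summary strings.
* Strict `>` at the 95% sinus gate; closed ±20% bound in the filter.
* Histogram bins aligned to multiples of the bin width; half-open spectral
  band edges with HF closed at 0.40 Hz.
* Single top-level seed per simulated cohort; per-subject and per-visit
  streams drawn deterministically from it, so cohorts are bit-reproducible.
* Problem sizes in the test-suite simulations (50-seed DFA batteries,
  1000–2000-replicate operating-characteristic runs, 29-subject single-arm
  cohorts) were chosen to give Monte-Carlo standard errors comfortably
  inside the asserted bands on a single CPU.

## Limitations

* 20-minute resting recordings only; no 24-h/circadian logic.
* No autoregressive or Lomb–Scargle spectra; the Welch estimator on a
  splined tachogram is the single spectral route.
* SampEn/DFA treat the edited series as contiguous (see above).
* The cohort simulator is a test harness for the pipeline and the trial
  statistics, not a physiological model of exercise training.
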