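---
title: "Simulating rhythm-delay stream-segregation psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rhythm-delay stream-segregation psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamseg)
```

## The paradigm

Auditory stream segregation is the perceptual sorting of an interleaved
sound sequence into separate streams. `streamseg` simulates an *objective,
segregation-facilitating* paradigm for measuring it: a trial presents an
alternating ABAB... sequence of narrowband-noise (NBN) bursts in which the
attended **B** subsequence is rhythmically regular — 260 ms onset to onset —
while the distracting **A** bursts are temporally jittered. On *signal*
trials the final B burst arrives 35 ms late; on *reference* trials it is
advanced by 0–10 ms. Only a listener who perceptually segregates the B
stream from the jittered A stream can track its rhythm well enough to
detect the late final burst, so single-interval yes/no sensitivity

$$d' = Z(\text{hit rate}) - Z(\text{false-alarm rate})$$

indexes voluntary segregation strength. Crossing two sequence durations
(3 or 9 AB pairs), three A–B spectral separations (none / moderate /
large) and three AM-rate separations (AM0-0 / AM200-50 / AM300-50) yields
the 18-condition grid of `build_condition_grid()`.

## Timing rules

`make_sequence_timing()` implements the schedule: 80-ms bursts; the first
A at time zero; the first B 130 ms later; B onsets every 260 ms; every A
after the first jittered by a signed offset of magnitude uniform on
0–40 ms, so each silent gap between an A burst and an adjacent nominal B
position spans 10–90 ms. Two points were genuinely open and are resolved
as follows:

* **Jitter sign.** Only the jitter magnitude distribution (uniform
  0–40 ms) is specified by the design; we draw an independent random sign
  per jittered burst so each adjacent gap individually spans the stated
  10–90 ms range.
* **Gap accounting for the final B.** The 10–90 ms gap rule is enforced
  against the *nominal* position of the final B burst: the final-B shift
  is the target the listener must detect, not a constraint on the jitter.

Under these rules the 9-pair delayed sequence lasts exactly
`r sequence_duration(make_sequence_timing(9, "delayed", seed = 1))` s and
no-delay 9-pair sequences fall in 2.28–2.29 s. The same rules give
0.765 s for the 3-pair delayed sequence (130 + 2·260 + 35 + 80 ms); a
printed figure of 0.665 s circulates for this condition, but it is
inconsistent with the rules that exactly reproduce the 9-pair durations,
so the package follows the rules.

## Synthesis

`synth_burst()` renders a burst as Gaussian noise passed through a
10th-order Butterworth bandpass (centre ± half the bandwidth; 162-Hz bands
below 5 kHz centre, 216-Hz above), followed by optional 100%-depth
sinusoidal AM, 8-ms raised-cosine ramps, and RMS calibration. Numerical
choices:

* **Second-order sections.** A 10th-order narrow bandpass is numerically
  unstable as a single transfer function in double precision; the package
  designs and applies the filter as cascaded biquads (`butter_sos()`,
  `sos_filter()`), causal/forward-only to match a real-time presentation
  chain.
* **AM after filtering.** The modulator multiplies the band-limited noise,
  so AM sidebands extend beyond the noise band, as when an envelope is
  imposed on an already-filtered carrier. The opposite order would narrow
  the sidebands slightly; the choice matters mildly for the electrodogram
  and is localised in `synth_burst()` should it need flipping.
* **Calibration.** 60 dB SPL maps to digital RMS 0.05 (`level_to_rms()`).
  Absolute SPL is meaningless without a measured playback chain; the
  constant is arbitrary but fixed, and leaves headroom so that level
  differences and modulation peaks never clip 24-bit output
  (`write_wav()` refuses clipped audio).

## Electrodogram simulation

`compute_electrodogram()` maps audio to implant stimulation in the style
of the ACE n-of-m strategy: a short-time FFT filterbank over the default
22-channel allocation spanning 188–7938 Hz (125-Hz analysis bands grouped
1,1,1,1,1,1,1,1,1,2,2,2,2,3,3,4,4,5,5,6,7,8 bins per channel), envelopes
at 900 frames/s, selection of the eight largest envelopes per frame, and
an activation floor. The allocation is validated by its channel centre
frequencies: the geometric band centres reproduce the clinical map's
printed values (electrode 12 ↦ 1683 Hz, electrode 8 ↦ 2869 Hz, electrode
2 ↦ 6486 Hz), which also anchors `assign_electrode()` against the cohort
table.

The activation floor (default 50 dB) is applied relative to the
stimulus's *peak* envelope across frames rather than per frame: a
per-frame-relative floor marks the broadband spectral splatter of the
onset/offset ramps as activation during low-level frames, whereas a
stimulus-relative floor behaves like the fixed base level of the clinical
loudness-growth map. At the default floor a paradigm NBN burst activates
a contiguous group of three to five electrodes centred on its assigned
electrode; the B-band and moderate-separation groups nearly touch while
the large-separation groups are several electrodes apart, so the
electrode-group distance grows monotonically with spectral separation. Published electrodograms from the
original clinical toolchain show slightly asymmetric groups (e.g. the B
burst activating #9–13 around assigned #12); no single principled floor
reproduces that asymmetry together with the other published sets, and the
package does not special-case it — the reconstruction centres the group on
the assigned electrode (#10–14). Current-level mapping, pulse
interleaving and neural spread are out of scope.

## Session engine

`run_session()` reproduces the procedure: training blocks of 40 trials
cycling through the 18 conditions in random order until one block of the
gate condition (large separation, AM0-0) reaches d′ ≥ 1.5 (cap 20
blocks); adaptive loudness balancing of the A level against the 60-dB-SPL
B reference; then the 18 conditions in pseudorandomised order — duration ×
spectral cells shuffled first, AM levels shuffled within each cell, the
two repetitions of each condition in consecutive blocks — as 65-trial
blocks whose first 5 trials are familiarization. Feedback is delivered to
the observer exactly once per trial, after its response.

The cited loudness-balancing procedure's staircase mechanics are not
specified in detail, so `loudness_balance()` uses a standard two-track
bracketing design: interleaved 1-up/2-down and 2-up/1-down tracks (which
converge at the 70.7% and 29.3% points, symmetric about the point of
subjective equality), 4-dB steps halved to 2 dB after two reversals, ten
reversals per track, PSE = mean of the last six reversal levels per
track. For an unbiased observer this returns 60 ± 1 dB; a +6-dB loudness
bias at the comparison frequency shifts the match to ≈ 54 dB, matching
the analytic PSE.

Reproducibility: every stochastic step (trial types, jitters, noise
seeds, staircases, block order) derives its seed from the session master
seed via counter-based splitting, so a session replays identically.

## Simulated observers

The synthetic-data module supplies listeners with known ground truth:

* `sdt_observer()` draws responses from the equal-variance Gaussian
  model: P(respond *delayed*) is Φ(d′/2 − c) on signal trials and
  Φ(−d′/2 − c) on reference trials. Its generating d′ is either an
  explicit 18-entry map or the linear rule
  d′ = max(0, β₀ + β_F·octaves_spectral + β_A·octaves_AM + β_D·1[9-pair] +
  β_G·1[NH]). The default coefficients (β₀ = 0.3, β_F = 0.9, β_A = −0.1,
  β_D = 0.45, β_G = 0.25) qualitatively mimic the pattern of interest — a
  graded spectral effect, a penalty for the largest AM separation, a
  build-up advantage for long sequences — and are illustrative, not fitted
  to any behavioural data.
* `envelope_observer()` is a mechanistic stand-in that hears only the
  audio: band-pass at the attended B band, full-wave rectification, 4th-
  order low-pass envelope (150 Hz), onset detection by upward threshold
  crossings (threshold 0.25 of the peak envelope) with a 120-ms
  refractory period — narrowband noise re-crosses any threshold within a
  burst, so the dead time spans a burst and its decay while staying below
  the 260-ms rhythm — then a decision on the final inter-onset interval
  plus Gaussian internal noise (default σ = 10 ms) against a 277.5-ms
  criterion, halfway between the nominal and delayed final intervals.
  When the distractor shares the B band it corrupts onset detection and
  accuracy falls toward chance; once the distractor is an octave or more
  away the band-pass removes it entirely, so moderate and large
  separations perform alike — the observer reproduces the
  *shared-band vs separated* contrast, not the full graded spectral
  effect, and the task's perceptual mechanism (gap discrimination vs
  rhythm tracking) is deliberately left open by offering both observer
  families.

What the generator does *not* emulate: attention lapses, learning from
feedback (both observers are stationary), loudness-growth differences
between electric and acoustic hearing, and any listener-specific use of
AM cues. Passing recovery tests therefore validates the pipeline's
bookkeeping and estimator, not a model of human listeners.

## Scoring

`score_block()` drops the familiarization trials and counts hits
("delayed" responses on delayed trials) and false alarms ("delayed" on
no-delay trials) over the remaining 60; `dprime()` applies an
extreme-rate correction and returns Z(h) − Z(f). Two corrections are
available:

* `"loglinear"` (default): add 0.5 to each count and 1 to each trial
  count. At this block size its absolute bias stays below 0.02 for
  generating d′ ≤ 2 (and below 0.07 up to d′ = 3).
* `"clamp"`: replace 0 with 1/(2N) and 1 with 1 − 1/(2N). This classic
  rule only touches extreme rates, but at 30 signal + 30 noise trials its
  estimator bias reaches +0.09 at d′ = 2 and +0.13 at d′ = 3, which is
  why it is not the default.

`summarize_session()` produces the 36-row (18 × 2) d′ table and
`buildup_effect()` the duration contrast — mean d′(9-pair) −
mean d′(3-pair), overall and per spectral separation — the build-up
analogue used throughout the tests.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to keep Monte-Carlo error well
below the tolerances they assert: timing invariants over 10⁴ draws;
spectral confinement from 300 averaged burst periodograms; estimator
recovery from 1000 simulated 60-trial blocks per generating d′ in
{0.5, 1, 1.5, 2} (tolerance ±0.1); training-gate operating
characteristics from 400 simulated training phases per observer; and
envelope-observer accuracy from 2000 3-pair trials per spectral
separation. The 3-pair sequences are used for waveform-based checks since
the effect of interest (shared-band corruption of onset tracking) does
not depend on sequence length.

## Known limitations

* The electrodogram is a functional reconstruction of n-of-m processing,
  not a port of the clinical toolchain: no pre-emphasis/AGC front end, no
  loudness-growth mapping, no pulse interleaving; activation sets can
  differ from clinical plots by one electrode at the group edges.
* The envelope observer's accuracy is insensitive to AM-rate separation
  and saturates beyond the moderate spectral separation.
* Group-level statistics are deliberately limited to descriptive
  summaries and the build-up contrast; mixed-effects modelling of human
  data is out of scope.
* A MED-EL-style 12-channel default allocation is not shipped: the
  cohort's MED-EL row implies a custom clinical map that no uniform
  log-spaced default reproduces. `ace_config()` accepts arbitrary band
  edges if such a map is available.
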