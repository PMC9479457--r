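# streamseg

Simulation toolkit for an objective auditory stream-segregation
experiment, aimed at hearing scientists and psychoacousticians who want a
tested, reproducible re-implementation of the paradigm for piloting,
power exploration and method checks — for both normal-hearing (NH)
listeners and cochlear-implant (CI) users.

## The paradigm and the statistic

A trial presents an alternating **ABAB...** sequence of 80-ms
amplitude-modulated narrowband-noise bursts. The attended **B** stream is
isochronous (260-ms onset-to-onset); the distracting **A** bursts are
jittered by up to ±40 ms. On *signal* trials the final B burst is delayed
by 35 ms; on *reference* trials it is advanced by 0–10 ms. A listener can
detect the late burst only by segregating the B stream and tracking its
rhythm, so yes/no sensitivity

    d' = Z(hit rate) − Z(false-alarm rate)

measures voluntary stream segregation. The design crosses sequence
duration (3 vs 9 AB pairs — the *build-up* contrast), A–B spectral
separation (none / moderate / large; e.g. 1803 vs 1803, 3022 or 6665 Hz
for NH listeners) and AM-rate separation (AM0-0, AM200-50, AM300-50)
into 18 conditions.

The package implements the whole chain:

* condition grid, listener profiles and burst-by-burst timing rules;
* calibrated noise-burst synthesis (10th-order Butterworth bands, 100%
  AM, raised-cosine ramps) and 24-bit WAV I/O;
* an ACE-style n-of-m electrodogram simulation (22 channels, 188–7938 Hz,
  900 pps, 8 maxima) for CI stimulation patterns;
* a yes/no session engine: training gate (d′ ≥ 1.5), adaptive loudness
  balancing, pseudorandomised blocks, trial-level CSV logs;
* simulated observers with known ground truth (signal-detection and
  envelope-mechanistic); and
* d′ scoring with extreme-rate corrections, session summaries and the
  build-up contrast.

## Worked example

Simulate a full session for a normal-hearing profile with a
signal-detection observer whose sensitivity follows the linear rule
d′ = max(0, 0.3 + 0.9·oct_spectral − 0.1·oct_AM + 0.45·1[9-pair] + 0.25·1[NH]):

```r
library(streamseg)

obs  <- sdt_observer(beta0 = 0.3, beta_spec = 0.9, beta_am = -0.1,
                     beta_dur = 0.45, beta_group = 0.25)
sess <- run_session(nh_profile(), obs, master_seed = 42)
sess
#> <session> NH: 3 training block(s) (gate passed), 36 scored block(s)

tab <- summarize_session(sess)
aggregate(dprime ~ spectral_sep, condition_means(tab), mean)
#>   spectral_sep    dprime
#> 1        large 2.4504982
#> 2     moderate 1.4255536
#> 3         none 0.4163422

buildup_effect(tab)$overall
#> [1] 0.3637377
```

The observer passed the training gate in 3 blocks, then completed the
36 scored blocks (18 conditions × 2 repetitions). Estimated d′ rises
with spectral separation (0.42 → 1.43 → 2.45, tracking the generating
rule's 0.9/octave slope), and the 9-pair blocks outscore the 3-pair
blocks by 0.36 on average — the recovered build-up effect (the generating
value is 0.45; a single 36-block session estimates it with SE ≈ 0.11).

Stimuli and stimulation patterns are first-class objects:

```r
tm <- make_sequence_timing(9, "delayed", seed = 1)
tm
#> <seq_timing> 9-pair delayed sequence, 2.325 s
#>   final-B shift +35.00 ms; |jitter| max 37.8 ms

wav <- render_sequence(tm, band_specs_for(nh_profile(), "large", "AM300-50"))
write_wav(wav, "sequence.wav")

eg <- compute_electrodogram(synth_burst(band_spec(1683, 162, am_rate = 50),
                                        seed = 62))
eg
#> <electrodogram> 204 pulses on 5 electrodes (#10, #11, #12, #13, #14)
```

The 1683-Hz B band stimulates five neighbouring electrodes around its
assigned electrode 12 at 900 pulses/s — the spread-of-activation pattern
that shrinks the effective inter-stream electrode separation for implant
listeners.

A thin command-line wrapper for the synth/egram/score steps ships in
`inst/cli/streamseg.R`.

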