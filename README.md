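# tecc — Teager energy cepstral features for noise-robust voice-pathology detection

`tecc` is an R toolkit for discriminating pathological (dysphonic) from
normal voices in noisy recording conditions. It implements three cepstral
front-ends — classical **MFCC**, Mel-scale Teager energy cepstra
(**MTECC**), and Gammatone Teager energy cepstra (**GTECC**) — a seeded
13-10-1 multilayer perceptron classifier, a synthetic dysphonic-voice
generator, and an evaluation harness that measures correct classification
rates (CCR) in clean and white-noise conditions. It is aimed at speech and
biomedical signal-processing researchers who need a reproducible,
self-contained testbed for auditory-model features.

## The method in brief

All front-ends share the cepstral stage

    C_n = sum_{i=1..K} log10(S_i) * cos[n (i - 1/2) pi / K],   n = 1..13,

applied to per-frame band values `S_i` (25 ms Hamming frames, 10 ms hop).
They differ in how `S_i` is produced:

* **MFCC** — FFT power accumulated by K = 30 triangular filters equally
  spaced on the mel scale `2595 log10(1 + f/700)`.
* **MTECC** — as MFCC, with the discrete Teager-Kaiser energy operator
  `psi[q(n)] = q(n)^2 - q(n+1) q(n-1)` (absolute value) applied across the
  band axis before the log.
* **GTECC** — a Gammatone auditory bank instead: impulse responses
  `A t^3 exp(-2 pi b F ERB(f_c) t) cos(2 pi f_c t)` with `b = 1.019`,
  `F = 1.5`, `ERB(f) = 6.23 (f/1000)^2 + 93.39 (f/1000) + 28.52` Hz, centers
  equidistant on the Bark scale; the Teager operator then runs along each
  time-domain band signal.

A 13-10-1 sigmoid MLP (full-batch gradient descent, target MSE 1e-4, at
most 5000 iterations, seeded initialization) classifies per-utterance mean
cepstra; performance is reported as `CCR = (CCR_normal + CCR_path) / 2` in
percent. The scientific claim the package lets you test is that GTECC
degrades far more gracefully than MFCC when white noise is added to the
test signals.

## Worked example

```r
library(tecc)

# a synthetic corpus: 60 normal + 60 pathological sustained vowels
ds <- make_voice_dataset(60, 60, seed = 101)
ds
#> <voice_dataset> 120 voices (60 normal, 60 pathological) @ 16000 Hz

# the full noise-robustness experiment for one replicate
report <- run_noise_sweep(ds, snr_levels_db = c(15, 10, 5, 0),
                          split_seed = 201, noise_seed = 301)
report
#> Noise-robustness evaluation (train 90 / test 30 voices)
#> Feature  Rate          clean    15 dB    10 dB     5 dB     0 dB
#> MFCC     CCR_Norm     100.00     0.00     0.00     0.00     0.00
#> MFCC     CCR_Path     100.00   100.00   100.00   100.00   100.00
#> MFCC     CCR          100.00    50.00    50.00    50.00    50.00
#> MTECC    CCR_Norm     100.00   100.00   100.00   100.00   100.00
#> MTECC    CCR_Path     100.00     0.00     0.00     0.00     0.00
#> MTECC    CCR          100.00    50.00    50.00    50.00    50.00
#> GTECC    CCR_Norm     100.00    80.00    80.00    73.33    60.00
#> GTECC    CCR_Path     100.00    93.33   100.00   100.00   100.00
#> GTECC    CCR          100.00    86.67    90.00    86.67    80.00
```

Reading the table: in the clean condition every front-end separates the
classes perfectly (the synthetic classes differ in jitter, shimmer and
aspiration noise). As test-set noise increases, MFCC collapses to chance —
every noisy voice, healthy or not, starts to look breathy and is pushed to
one side of the decision boundary — while GTECC retains most of its
accuracy, the robustness ordering the package is built to demonstrate.
Single-replicate numbers are noisy; headline values should be medians over
seeds (see below).

Lower-level pieces are exposed individually:

```r
v  <- synthesize_voice(voice_spec(f0 = 140, jitter_pct = 4, shimmer_pct = 10,
                                  aspiration_snr_db = 10, seed = 7))
f  <- extract_gtecc(v)          # cepstral matrix
dim(f)
#> [1] 48 13
p  <- pool_utterance(f)         # one 13-vector
noisy <- mix_noise_at_snr(v, snr_db = 0, seed = 1)
compute_snr(v$samples, attr(noisy, "noise"))
#> [1] 0
```

A thin CLI over the same functions lives at
`system.file("cli/tecc-cli.R", package = "tecc")` with `synth`, `extract`,
`train`, `predict` and `evaluate` subcommands.

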