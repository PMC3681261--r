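---
title: "Auditory Teager energy cepstra for voice-pathology detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory Teager energy cepstra for voice-pathology detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dysphonic (pathological) voices — from vocal-fold polyps, edema, paralysis,
neurological disease and similar conditions — differ acoustically from
normophonic voices mainly through elevated cycle-to-cycle perturbation
(jitter in period, shimmer in amplitude) and aspiration noise from
incomplete glottal closure. Automatic normal/pathological screening from a
recording is attractive because it is noninvasive and quantitative, but
standard spectral features such as MFCCs degrade quickly when the recording
itself is noisy. `tecc` implements a family of auditory front-ends built
around the Teager-Kaiser energy operator and a Gammatone cochlear filter
bank that are empirically far more stable under additive white noise, plus
the small neural classifier and the evaluation protocol needed to quantify
that robustness.

## The three front-ends

All three pipelines share a short-time analysis: 25 ms Hamming frames every
10 ms (defaults, configurable), FFT length the next power of two at or
above the frame length, and a final cepstral stage

$$C_n = \sum_{i=1}^{K} \log_{10}(S_i)\,
        \cos\!\left[n\left(i - \tfrac12\right)\frac{\pi}{K}\right],
        \qquad n = 1, \dots, 13,$$

where $S_i$ are the $K$ per-band values of the frame. The DCT is coded
literally in this form (1-based $n$, no orthonormalization), and because
$n = 0$ is excluded, a common multiplicative factor on all $S_i$ — an
overall gain change — leaves every coefficient unchanged exactly.

* **MFCC** — FFT magnitude (squared by default, see *Numerical choices*)
  accumulated by a $K$-triangle filter bank whose centers are equally
  spaced on the mel scale $2595\log_{10}(1 + f/700)$, then log/DCT.
* **MTECC** — as MFCC, but with the discrete Teager-Kaiser operator
  $\psi_d[q(n)] = q^2(n) - q(n+1)q(n-1)$, in absolute value, applied
  *across the band axis* of each frame's triangular-bank output before the
  log.
* **GTECC** — a Gammatone filter bank replaces the triangular one. Each
  filter has impulse response
  $g(t) = A\,t^{\,n-1} e^{-2\pi b F\,\mathrm{ERB}(f_c) t} \cos(2\pi f_c t)$
  with order $n = 4$, bandwidth coefficient $b = 1.019$, center frequencies
  equidistant on the Bark scale $26.81 f/(f+3920) - 0.53$, and bandwidths
  $F \cdot \mathrm{ERB}(f_c)$ where
  $\mathrm{ERB}(f) = 6.23 (f/1000)^2 + 93.39 (f/1000) + 28.52$ Hz. The
  default bank uses $K = 30$ filters and $F = 1.5$, the configuration
  reported to behave best for robust recognition; the 25-filter variant is
  one argument away. By default the Teager operator runs *along time*
  within each gammatone-filtered band signal ($|\psi_d|$ averaged per
  frame), which is the physically meaningful energy-tracking placement: for
  an AM-FM component $a(t)\cos\phi(t)$, $\psi$ approximates
  $(a\,\mathrm{d}\phi/\mathrm{d}t)^2$, an energy that weights amplitude
  *and* frequency.

### Where to put the Teager operator

The literature is genuinely ambiguous between applying the operator to the
short-time spectrum and applying it to time-domain band signals. We
implement both: `feature_config(teo_mode = )` switches GTECC between the
temporal placement (default) and the spectral one. The Mel triangular bank
has no time-domain kernels — it exists only as spectral weights — so MTECC
always uses the spectral placement (operator across the band axis). The
evaluation report records the configuration fingerprint, so which mode
produced any table is always auditable.

### Frame pooling

The classifier takes one 13-vector per voice, so frame-level features must
be pooled; nothing in the architecture dictates how. We pool by the
per-coefficient **mean** over frames (median optional via
`feature_config(pooling = )`). This is the minimal reading of a
13-input network and is stated prominently because every downstream number
depends on it.

## The gammatone bank: realized versus design bandwidth

Filter weights are computed from a dense DFT of the *sampled* impulse
response rather than from the closed-form frequency response, whose
constant-factor conventions are ambiguous; the gain $A$ is set by exact
peak normalization, $|H(f_c)| = 1$, the property the analytic gain formula
is derived to achieve. Two discretization effects matter and drove design
choices, both verified by the test suite's numerically integrated ERB
(`measured_erb()`, the rectangular-equivalent bandwidth
$\int |H|^2 \mathrm{d}f / \max|H|^2$):

* **Kernel truncation.** Cutting the kernel at 99.9% of its envelope
  energy widens the realized ERB by about 4% through spectral leakage.
  Default kernels therefore cover the envelope energy to $1 - 10^{-8}$
  (a few hundred samples at 16 kHz).
* **Band-edge clearance.** A filter centered too close to Nyquist loses
  passband energy to truncation, and one too close to DC gains energy from
  its negative-frequency image; either distorts the realized ERB by far
  more than 5%. Centers are therefore placed on the Bark grid between
  $f_{\min}$ (raised, if necessary, to $2.0$ decay half-widths
  $b F\,\mathrm{ERB}(f_c)$ above DC) and the frequency whose band stays
  $1.6$ half-widths below $f_{\max}$. At 16 kHz with defaults this puts the
  30 centers between roughly 122 Hz and 6 kHz, and every realized ERB then
  matches its design value within 0.4%.

## The synthetic voice corpus

Clinical corpora of diagnosed voices are not distributable, so the package
ships a generator whose two classes are separable by the same cues
clinicians describe. Each voice is a source-filter synthesis of a sustained
/a/: a Rosenberg glottal pulse train at $f_0$ whose per-cycle period and
amplitude receive multiplicative Gaussian perturbations (truncated at
$\pm 3\sigma$) of standard deviation `jitter_pct`/100 and
`shimmer_pct`/100 — the usual dysphonia-simulation convention — plus white
aspiration noise at a controlled harmonic-to-noise power ratio, filtered
through four formant resonators (730, 1090, 2440, 3400 Hz) and
peak-normalized. Cycle lengths are rounded with error diffusion so the
long-run rate is exact.

Default class conditions: normal voices draw jitter 0.05–1%, shimmer
0.5–3%, aspiration SNR 25–40 dB; pathological voices jitter 2–8%, shimmer
5–20%, aspiration SNR 5–15 dB; both draw $f_0$ from 90–230 Hz. The default
sample rate is 16 kHz (configurable to 48 kHz) and the default duration
0.5 s — enough for ~48 analysis frames while keeping a 120-voice corpus
synthesizable in under a second.

What the generator does *not* emulate: sentence material and prosody,
distinct pathology subtypes, room acoustics, recording-chain coloration,
and the nonstationarity of real phonation onsets/offsets. Passing tests on
this corpus therefore show that the front-ends and classifier recover a
*perturbation-based* class distinction under controlled noise — the
mechanism behind the robustness claim — not that any particular clinical
accuracy would be attained on hospital recordings.

## Classifier and evaluation protocol

The classifier is a 13-10-1 multilayer perceptron, sigmoid throughout,
trained by full-batch gradient descent on the mean-squared error until it
reaches the target MSE $10^{-4}$ or 5000 iterations. Unstated details are
fixed as: learning rate 0.05, momentum 0.9, uniform$(-0.5, 0.5)$ weights
scaled by $1/\sqrt{\text{fan-in}}$, z-score input standardization with
training-set statistics stored in the model, decision threshold 0.5 with
ties labeled pathological (favoring sensitivity). Backpropagation is
guarded by a central-finite-difference gradient check (agreement to
$10^{-6}$ relative).

The evaluation harness performs a seeded 75/25 stratified split, trains on
clean training features, and reports the correct classification rate

$$\mathrm{CCR} = \tfrac12\left(\mathrm{CCR}_{\text{norm}} +
  \mathrm{CCR}_{\text{path}}\right)$$

(per-class accuracies in percent) on the clean test set and after mixing
white Gaussian noise into the test waveforms at 15, 10, 5 and 0 dB SNR.
Noise is scaled against the realized noise power over the whole utterance,
so the requested SNR is met exactly ($< 10^{-6}$ dB) per realization.
Training on matched noisy data is available via `train_noisy = TRUE` but is
not the default protocol. Because there is a single synthetic corpus rather
than several recorded ones, headline numbers are medians over seeded
replicates (10 in the acceptance script); one replicate at the default
sizes takes roughly 10–20 s on one CPU.

```{r, eval = FALSE}
library(tecc)
ds <- make_voice_dataset(60, 60, seed = 101)
run_noise_sweep(ds, split_seed = 201, noise_seed = 301)
```

## Numerical choices

* Band accumulation defaults to **power** (squared magnitudes); plain
  magnitude accumulation is available (`band_energy = "magnitude"`) since
  the convention is not universal.
* Band energies are floored at $10^{-12}$ before `log10`, so silence and
  TEO-annihilated bands stay finite; the floor is far below any energy a
  voiced frame produces, so amplitude-scaling invariance is unaffected in
  practice.
* The Teager operator's first and last samples replicate their nearest
  interior value, keeping sequence lengths aligned; its absolute value is
  taken before the log stage (the operator is sign-indefinite pointwise).
* No pre-emphasis by default (exposed as an option); no liftering, no
  delta coefficients.
* SNR is computed over the full utterance with no voicing qualifier.
* The mel bank errors out rather than silently producing empty triangles
  when `n_filters` outruns the FFT grid; `stft_magnitude` refuses an
  `nfft` below the frame length rather than truncating.

## Measuring feature stability across front-ends

One property test compares how far pooled features move when 0 dB noise is
added. Raw Euclidean displacement is not comparable across front-ends —
MTECC's operator-of-energies roughly doubles the log scale, inflating its
raw displacement — so displacement is measured after dividing each
coefficient by its clean between-utterance standard deviation, i.e. in the
units the standardized classifier actually sees. In those units the median
displacement ordering is GTECC < MTECC < MFCC, the mechanism behind the
CCR ordering the evaluation reproduces.

## Known limitations

* The synthetic corpus is stationary sustained phonation; results do not
  transfer quantitatively to running speech or clinical recordings.
* Only white Gaussian noise is modeled; babble or street noise will
  behave differently.
* The gammatone bank is FIR-by-sampling, not the cheap recursive
  approximation; extraction cost grows with kernel length at low center
  frequencies (mitigated by an internal design cache).
* The classifier deliberately matches the stated architecture; no
  cross-validation, regularization or hyperparameter search is provided.
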