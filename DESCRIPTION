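Package: tecc
Title: Teager Energy Cepstral Features for Noise-Robust Detection of
    Pathological Voices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Acoustic front-ends and a neural classifier for discriminating
    pathological (dysphonic) from normal voices in noisy environments.
    Implements three cepstral feature extractors -- classical MFCC, Mel-scale
    Teager energy cepstral coefficients (MTECC), and Gammatone Teager energy
    cepstral coefficients (GTECC) built on an ERB/Bark auditory filter bank
    and the discrete Teager-Kaiser energy operator -- together with a seeded
    13-10-1 multilayer perceptron trained by gradient descent, a synthetic
    dysphonic-voice generator (source-filter model with controllable jitter,
    shimmer and aspiration noise), exact-SNR white-noise mixing, and an
    evaluation harness that reports correct classification rates per feature
    type across clean and noisy conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
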