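test_that("voice_spec validation names the offending field", {
  expect_error(voice_spec(f0 = -1), "f0")
  expect_error(voice_spec(duration = 0), "duration")
  expect_error(voice_spec(jitter_pct = -2), "jitter_pct")
  expect_error(voice_spec(shimmer_pct = -1), "shimmer_pct")
  expect_error(voice_spec(sample_rate = 4000), "sample_rate")
  expect_error(voice_spec(formants = list(c(500))), "formants")
})

test_that("synthesis is bit-identical under the same spec and seed", {
  sp <- voice_spec(f0 = 150, jitter_pct = 2, shimmer_pct = 5,
                   aspiration_snr_db = 20, seed = 17)
  v1 <- synthesize_voice(sp)
  v2 <- synthesize_voice(sp)
  expect_identical(v1$samples, v2$samples)
  v3 <- synthesize_voice(voice_spec(f0 = 150, jitter_pct = 2, shimmer_pct = 5,
                                    aspiration_snr_db = 20, seed = 18))
  expect_false(identical(v1$samples, v3$samples))
})

test_that("synthesized voices are peak-normalized", {
  v <- synthesize_voice(voice_spec(seed = 4))
  expect_equal(max(abs(v$samples)), 1)
})

test_that("an unperturbed source has its fundamental at the requested f0", {
  v <- synthesize_voice(voice_spec(f0 = 120, jitter_pct = 0, shimmer_pct = 0,
                                   aspiration_snr_db = 60, seed = 3))
  expect_lt(abs(est_f0_acf(v) - 120), 1)
})

test_that("the clean-source spectrum peaks at harmonics of f0", {
  v <- synthesize_voice(voice_spec(f0 = 120, duration = 0.5, jitter_pct = 0,
                                   shimmer_pct = 0, aspiration_snr_db = 60,
                                   seed = 3))
  m <- Mod(stats::fft(v$samples))[1:(length(v$samples) / 2)]
  bin_hz <- v$sample_rate / length(v$samples)
  for (k in 1:5) {
    b <- round(k * 120 / bin_hz) + 1
    window <- m[(b - 3):(b + 3)]
    expect_lte(abs(which.max(window) - 4), 1)  # peak within one FFT bin
  }
})

test_that("perturbations strictly lower the harmonic-to-noise ratio", {
  clean <- synthesize_voice(voice_spec(f0 = 120, jitter_pct = 0,
                                       shimmer_pct = 0,
                                       aspiration_snr_db = 60, seed = 3))
  pert <- synthesize_voice(voice_spec(f0 = 120, jitter_pct = 5,
                                      shimmer_pct = 10,
                                      aspiration_snr_db = 60, seed = 3))
  expect_lt(est_hnr(pert), est_hnr(clean))
})

test_that("more aspiration noise monotonically lowers measured HNR", {
  hnrs <- vapply(c(40, 25, 15, 5), function(asp) {
    est_hnr(synthesize_voice(voice_spec(f0 = 140, aspiration_snr_db = asp,
                                        seed = 9)))
  }, numeric(1))
  expect_true(all(diff(hnrs) < 0))
})

test_that("jitter increases the spread of detected glottal cycle lengths", {
  sds <- vapply(c(0, 3, 6), function(j) {
    v <- synthesize_voice(voice_spec(f0 = 120, jitter_pct = j, duration = 1,
                                     aspiration_snr_db = 40, seed = 5))
    est_period_sd(v, 120)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("dataset generation balances labels and is reproducible", {
  ds1 <- make_voice_dataset(10, 10, seed = 1, duration = 0.3)
  expect_length(ds1, 20)
  lab <- dataset_labels(ds1)
  expect_equal(sum(lab == "normal"), 10)
  expect_equal(sum(lab == "pathological"), 10)
  ds2 <- make_voice_dataset(10, 10, seed = 1, duration = 0.3)
  expect_identical(lapply(ds1, function(it) it$signal$samples),
                   lapply(ds2, function(it) it$signal$samples))
})

test_that("overlapping perturbation ranges trigger a warning", {
  overlapping <- normal_voice_ranges()
  overlapping$jitter_pct <- c(0.5, 4)
  expect_warning(make_voice_dataset(4, 4, normal_ranges = overlapping,
                                    seed = 1, duration = 0.2),
                 "overlap")
})

test_that("default classes are separable by mean band log-energies", {
  ds <- make_voice_dataset(30, 30, seed = 21, duration = 0.4)
  feats <- t(vapply(ds, function(it) {
    fm <- frame_signal(it$signal)
    sp <- stft_magnitude(fm)
    bank <- design_mel_filterbank(
      filterbank_spec("mel_triangular", sample_rate = it$signal$sample_rate),
      sp$nfft)
    colMeans(log10(pmax(apply_filterbank(sp, bank), 1e-12)))
  }, numeric(30)))
  y <- as.integer(dataset_labels(ds) == "pathological")
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                     data = data.frame(y = y, feats)))
  pred <- as.integer(stats::fitted(fit) >= 0.5)
  expect_gt(mean(pred == y), 0.8)
})

test_that("WAV round trip preserves signals to quantization accuracy", {
  v <- synthesize_voice(voice_spec(duration = 0.1, seed = 2))
  p16 <- tempfile(fileext = ".wav")
  write_wav(v, p16, bit_depth = 16)
  r16 <- read_wav(p16)
  expect_equal(r16$sample_rate, v$sample_rate)
  expect_lt(max(abs(r16$samples - v$samples)), 1 / 32767)
  p32 <- tempfile(fileext = ".wav")
  write_wav(v, p32, bit_depth = 32)
  r32 <- read_wav(p32)
  expect_lt(max(abs(r32$samples - v$samples)), 1e-6)
  unlink(c(p16, p32))
})

test_that("dataset export writes a complete manifest and reloads", {
  ds <- make_voice_dataset(4, 4, seed = 5, duration = 0.15)
  dir <- tempfile("voices")
  write_voice_dataset(ds, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 8)
  expect_true(all(c("filename", "label", "f0", "jitter_pct", "shimmer_pct",
                    "aspiration_snr_db", "seed") %in% names(manifest)))
  back <- read_voice_dataset(dir)
  expect_identical(dataset_labels(back), dataset_labels(ds))
  expect_lt(max(abs(back[[1]]$signal$samples - ds[[1]]$signal$samples)),
            1 / 32767)
  unlink(dir, recursive = TRUE)
})
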