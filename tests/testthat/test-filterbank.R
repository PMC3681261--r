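test_that("auditory scale functions match their defining formulas", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 2595 * log10(2))
  expect_equal(erb_hz(0), 28.52)
  expect_equal(erb_hz(1000), 128.14)
  expect_equal(bark_scale(0), -0.53)
  expect_equal(bark_scale(3920), 26.81 / 2 - 0.53)
  expect_error(mel_scale(-1), "frequency")
  expect_error(erb_hz(-10), "frequency")
  expect_error(bark_scale(-0.1), "frequency")
})

test_that("scales are monotone and invertible where defined", {
  f <- seq(0, 24000, length.out = 500)
  expect_true(all(diff(mel_scale(f)) > 0))
  expect_true(all(diff(erb_hz(f)) > 0))
  expect_true(all(diff(bark_scale(f)) > 0))
  expect_lt(bark_scale(1e9), 26.28)
  withr::with_seed(1, {
    fr <- runif(200, 0, 24000)
    expect_equal(mel_to_hz(mel_scale(fr)), fr, tolerance = 1e-9)
    expect_equal(bark_to_hz(bark_scale(fr)), fr, tolerance = 1e-9)
  })
})

test_that("mel triangle centers form an arithmetic progression in mel", {
  bank <- design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = 26, f_min = 50,
                    f_max = 8000, sample_rate = 16000), 512)
  mels <- mel_scale(bank$center_frequencies)
  expect_lt(max(abs(diff(mels) - mean(diff(mels)))), 1e-6)
  expect_true(all(diff(bank$center_frequencies) > 0))
})

test_that("mel triangles match an independent geometric construction", {
  bank <- design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = 12, f_min = 100,
                    f_max = 7000, sample_rate = 16000), 256)
  oracle <- bf_mel_weights(100, 7000, 12, 256, 16000)
  expect_equal(unname(bank$weights), oracle, tolerance = 1e-10)
})

test_that("each interior triangle peaks at its own center bin", {
  bank <- design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = 20, f_min = 50,
                    f_max = 8000, sample_rate = 16000), 1024)
  for (j in 2:19) {
    cb <- which.min(abs(bank$freqs - bank$center_frequencies[j]))
    expect_equal(which.max(bank$weights[j, ]), cb, tolerance = 1)
  }
})

test_that("gammatone kernels start at zero and have unit gain at center", {
  spec <- filterbank_spec("gammatone", sample_rate = 16000)
  kern <- gammatone_impulse_response(1000, spec)
  expect_equal(kern[1], 0)                       # t^(n-1) factor, n = 4
  t <- (seq_along(kern) - 1) / 16000
  gain <- Mod(sum(kern * exp(-2i * pi * 1000 * t)))
  expect_equal(gain, 1, tolerance = 1e-3)
  # dense DFT oracle: grid maximum is also ~1
  h <- Mod(stats::fft(c(kern, numeric(2^16 - length(kern)))))
  expect_equal(max(h[1:2^15]), 1, tolerance = 1e-3)
})

test_that("a kernel too short for its envelope is rejected", {
  spec <- filterbank_spec("gammatone", sample_rate = 16000)
  expect_error(gammatone_impulse_response(200, spec, length = 40),
               "too short")
})

test_that("designed gammatone filters realize their ERB(f) bandwidths", {
  bank <- design_gammatone_bank(
    filterbank_spec("gammatone", n_filters = 30, bandwidth_multiplier = 1.5,
                    sample_rate = 16000), 512)
  for (i in seq_along(bank$center_frequencies)) {
    me <- measured_erb(bank$impulse_responses[[i]], 16000)
    expect_lt(abs(me - bank$bandwidths[i]) / bank$bandwidths[i], 0.05)
  }
})

test_that("gammatone centers are equidistant on the Bark axis", {
  bank <- design_gammatone_bank(
    filterbank_spec("gammatone", n_filters = 30, sample_rate = 16000), 512)
  z <- bark_scale(bank$center_frequencies)
  expect_lt(max(abs(diff(z) - mean(diff(z)))), 1e-6)
  expect_true(all(bank$center_frequencies > 0 &
                    bank$center_frequencies < 8000))
})

test_that("the 25-filter, 1.5*ERB configuration has the expected structure", {
  bank <- design_gammatone_bank(
    filterbank_spec("gammatone", n_filters = 25, bandwidth_multiplier = 1.5,
                    sample_rate = 16000), 512)
  expect_equal(nrow(bank$weights), 25)
  expect_true(all(diff(bank$center_frequencies) > 0))
  expect_true(all(diff(bank$bandwidths) > 0))
})

test_that("defaults follow the recommended configuration", {
  spec <- filterbank_spec("gammatone", sample_rate = 16000)
  expect_equal(spec$n_filters, 30L)
  expect_equal(spec$bandwidth_multiplier, 1.5)
  expect_equal(spec$b, 1.019)
  expect_equal(spec$order, 4L)
})

test_that("band edges outside [0, Nyquist] are rejected", {
  expect_error(filterbank_spec("gammatone", f_min = 50, f_max = 9000,
                               sample_rate = 16000), "f_max")
  expect_error(filterbank_spec("mel_triangular", f_min = -5,
                               sample_rate = 16000), "f_min")
})

test_that("filter bank application equals the brute-force accumulation", {
  withr::with_seed(3, {
    nfft <- 64
    bank <- design_mel_filterbank(
      filterbank_spec("mel_triangular", n_filters = 6, f_min = 100,
                      f_max = 3500, sample_rate = 8000), nfft)
    mags <- matrix(runif(5 * 33), 5, 33)
    sp <- fake_spectrum(mags, nfft, 8000)
    got <- apply_filterbank(sp, bank, "power")
    expected <- matrix(0, 5, 6)
    for (f in 1:5) for (j in 1:6) for (b in 1:33) {
      expected[f, j] <- expected[f, j] + bank$weights[j, b] * mags[f, b]^2
    }
    expect_equal(unclass(got), expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # magnitude mode drops the squaring
    gotm <- apply_filterbank(sp, bank, "magnitude")
    expect_equal(unclass(gotm), mags %*% t(bank$weights), tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("band accumulation is linear and maps zero to zero", {
  nfft <- 64
  bank <- design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = 6, f_min = 100,
                    f_max = 3500, sample_rate = 8000), nfft)
  z <- fake_spectrum(matrix(0, 3, 33), nfft, 8000)
  expect_true(all(apply_filterbank(z, bank) == 0))
  withr::with_seed(4, {
    a <- matrix(runif(3 * 33), 3, 33)
    b <- matrix(runif(3 * 33), 3, 33)
    lhs <- apply_filterbank(fake_spectrum(sqrt(a^2 + b^2), nfft, 8000), bank)
    rhs <- apply_filterbank(fake_spectrum(a, nfft, 8000), bank) +
      apply_filterbank(fake_spectrum(b, nfft, 8000), bank)
    expect_equal(unclass(lhs), unclass(rhs), tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
  expect_error(apply_filterbank(fake_spectrum(matrix(0, 2, 20), 64, 8000),
                                bank), "bins")
})

test_that("energy confined to one filter's support excites only that band", {
  nfft <- 128
  bank <- design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = 5, f_min = 100,
                    f_max = 3800, sample_rate = 8000), nfft)
  # the rising edge of the first triangle is the one region no other
  # filter reaches (interior triangles share support with their neighbors)
  j <- 1
  mags <- matrix(0, 1, 65)
  support <- which(bank$weights[j, ] > 0 &
                     colSums(bank$weights[-j, , drop = FALSE]) == 0)
  mags[1, support[1]] <- 1
  e <- apply_filterbank(fake_spectrum(mags, nfft, 8000), bank)
  expect_gt(e[1, j], 0)
  expect_true(all(e[1, -j] == 0))
})

test_that("filter banks survive a CSV export/import round trip", {
  bank <- design_gammatone_bank(
    filterbank_spec("gammatone", n_filters = 8, sample_rate = 16000), 256)
  path <- tempfile(fileext = ".csv")
  export_filterbank(bank, path)
  back <- import_filterbank(path)
  expect_equal(back$center_frequencies, bank$center_frequencies,
               tolerance = 1e-10)
  expect_equal(unname(back$weights), unname(bank$weights), tolerance = 1e-10)
  unlink(path)
})
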