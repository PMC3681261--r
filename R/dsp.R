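window_function <- function(name, n) {
  switch(match.arg(name, c("hamming", "hann", "rectangular")),
         hamming = as.numeric(signal::hamming(n)),
         hann = as.numeric(signal::hanning(n)),
         rectangular = rep(1, n))
}

#' Slice a signal into overlapping windowed frames
#'
#' Frames of `frame_ms` milliseconds taken every `hop_ms` milliseconds; each
#' frame is multiplied elementwise by the analysis window. A trailing partial
#' frame is dropped, so `n_frames = floor((N - L) / hop) + 1`.
#'
#' @param signal an [audio_signal].
#' @param frame_ms frame length in milliseconds (default 25).
#' @param hop_ms hop between frame starts in milliseconds (default 10).
#' @param window `"hamming"` (default), `"hann"` or `"rectangular"`.
#' @return an object of class `frame_matrix`: list with `frames`
#'   (`n_frames x frame_length` matrix), `frame_length`, `hop`,
#'   `sample_rate`, `window`.
#' @export
frame_signal <- function(signal, frame_ms = 25, hop_ms = 10,
                         window = "hamming") {
  signal <- as_audio_signal(signal)
  if (frame_ms <= 0 || hop_ms <= 0)
    stop("frame_ms and hop_ms must be positive")
  fs <- signal$sample_rate
  fl <- as.integer(round(fs * frame_ms / 1000))
  hop <- max(1L, as.integer(round(fs * hop_ms / 1000)))
  x <- signal$samples
  if (length(x) < fl)
    stop(sprintf("signal (%d samples) shorter than one frame (%d samples)",
                 length(x), fl))
  starts <- seq.int(0L, length(x) - fl, by = hop)
  idx <- outer(seq_len(fl), starts, `+`)
  win <- window_function(window, fl)
  fr <- matrix(x[idx], nrow = fl) * win    # window recycles down columns
  structure(list(frames = t(fr), frame_length = fl, hop = hop,
                 sample_rate = fs, window = window),
            class = "frame_matrix")
}

#' One-sided short-time magnitude spectrum
#'
#' FFT of each (already windowed) frame, zero-padded to `nfft`; returns the
#' magnitudes of bins `0..nfft/2`.
#'
#' @param frames a [frame_signal()] result.
#' @param nfft FFT length; must be a power of two and at least the frame
#'   length. Default: next power of two >= frame length.
#' @return an object of class `stft_spectrum`: list with `magnitudes`
#'   (`n_frames x (nfft/2 + 1)`), `nfft`, `sample_rate`, `freqs` (bin
#'   frequencies in Hz).
#' @export
stft_magnitude <- function(frames, nfft = NULL) {
  stopifnot(inherits(frames, "frame_matrix"))
  fl <- frames$frame_length
  if (is.null(nfft)) nfft <- 2^ceiling(log2(fl))
  nfft <- as.integer(nfft)
  if (nfft < fl)
    stop(sprintf("nfft (%d) must be >= frame length (%d); no silent truncation",
                 nfft, fl))
  if (bitwAnd(nfft, nfft - 1L) != 0L)
    stop("nfft must be a power of two")
  nf <- nrow(frames$frames)
  padded <- matrix(0, nrow = nfft, ncol = nf)
  padded[seq_len(fl), ] <- t(frames$frames)
  spec <- stats::mvfft(padded)
  nb <- nfft %/% 2L + 1L
  structure(list(magnitudes = t(Mod(spec[seq_len(nb), , drop = FALSE])),
                 nfft = nfft, sample_rate = frames$sample_rate,
                 freqs = (seq_len(nb) - 1) * frames$sample_rate / nfft),
            class = "stft_spectrum")
}

#' Signal-to-noise ratio of paired signal and noise segments
#'
#' `10 * log10(sum(s^2) / sum(n^2))` over the analysed segment.
#'
#' @param signal_part,noise_part numeric vectors of equal length.
#' @return SNR in dB.
#' @examples
#' compute_snr(c(2, 2), c(1, 1)) # 10 * log10(4)
#' @export
compute_snr <- function(signal_part, noise_part) {
  if (length(signal_part) != length(noise_part))
    stop("signal_part and noise_part must have the same length")
  pn <- sum(noise_part^2)
  if (pn <= 0) stop("noise power is zero; SNR undefined")
  10 * log10(sum(signal_part^2) / pn)
}

#' Mix seeded white Gaussian noise into a signal at an exact SNR
#'
#' The realized noise is rescaled so that the SNR computed on the actual
#' signal/noise components over the full signal equals `snr_db` exactly
#' (realized-power scaling, not expected-power). `snr_db = Inf` is a clean
#' passthrough. The scaled noise component is attached as attribute `"noise"`
#' for round-trip verification.
#'
#' @param signal an [audio_signal] with nonzero power.
#' @param snr_db target signal-to-noise ratio in dB (may be `Inf`).
#' @param seed integer RNG seed for the noise.
#' @return an [audio_signal] (`signal + noise`), with attribute `noise`.
#' @export
mix_noise_at_snr <- function(signal, snr_db, seed = 1L) {
  signal <- as_audio_signal(signal)
  x <- signal$samples
  if (is.infinite(snr_db) && snr_db > 0) {
    out <- signal
    attr(out, "noise") <- numeric(length(x))
    return(out)
  }
  ps <- sum(x^2)
  if (ps <= 0) stop("all-zero signal: SNR undefined")
  w <- withr::with_seed(as.integer(seed), rnorm(length(x)))
  g <- sqrt(ps / (sum(w^2) * 10^(snr_db / 10)))
  noise <- g * w
  out <- audio_signal(x + noise, signal$sample_rate)
  attr(out, "noise") <- noise
  out
}
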