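#' Front-end configuration
#'
#' All tunable parameters of the three cepstral front-ends. Defaults follow
#' the standard short-time analysis convention (25 ms Hamming frames every
#' 10 ms, FFT length the next power of two) with 30 auditory bands between
#' 50 Hz and Nyquist, ERB multiplier 1.5, and 13 retained cepstral
#' coefficients.
#'
#' @param frame_ms,hop_ms analysis frame length and hop in milliseconds.
#' @param window analysis window name (see [frame_signal()]).
#' @param nfft FFT length; `NULL` means next power of two >= frame length.
#' @param preemphasis first-order pre-emphasis coefficient in \[0, 1);
#'   0 (default) disables it.
#' @param n_filters number of filter-bank channels K.
#' @param f_min,f_max band edges in Hz (`NULL` `f_max` means Nyquist).
#' @param erb_multiplier gammatone bandwidth multiplier F.
#' @param gammatone_order,gammatone_b gammatone shape parameters n and b.
#' @param band_energy `"power"` or `"magnitude"` spectrum accumulation.
#' @param n_coeffs number of cepstral coefficients kept (default 13).
#' @param teo_mode `"temporal"` (Teager operator on time-domain gammatone
#'   band signals, default) or `"spectral"` (operator across the band axis of
#'   each frame). The Mel triangular bank exists only in the spectral domain,
#'   so MTECC always uses the spectral placement.
#' @param log_floor positive floor applied to band energies before `log10`.
#' @param pooling `"mean"` or `"median"` frame pooling for utterance vectors.
#' @return an object of class `feature_config` (a named list).
#' @export
feature_config <- function(frame_ms = 25, hop_ms = 10, window = "hamming",
                           nfft = NULL, preemphasis = 0, n_filters = 30,
                           f_min = 50, f_max = NULL, erb_multiplier = 1.5,
                           gammatone_order = 4, gammatone_b = 1.019,
                           band_energy = "power", n_coeffs = 13,
                           teo_mode = "temporal", log_floor = 1e-12,
                           pooling = "mean") {
  cfg <- list(frame_ms = frame_ms, hop_ms = hop_ms, window = window,
              nfft = nfft, preemphasis = preemphasis, n_filters = n_filters,
              f_min = f_min, f_max = f_max, erb_multiplier = erb_multiplier,
              gammatone_order = gammatone_order, gammatone_b = gammatone_b,
              band_energy = match.arg(band_energy, c("power", "magnitude")),
              n_coeffs = n_coeffs,
              teo_mode = match.arg(teo_mode, c("temporal", "spectral")),
              log_floor = log_floor,
              pooling = match.arg(pooling, c("mean", "median")))
  if (cfg$log_floor <= 0) stop("log_floor must be > 0")
  if (cfg$preemphasis < 0 || cfg$preemphasis >= 1)
    stop("preemphasis must be in [0, 1)")
  structure(cfg, class = "feature_config")
}

#' Canonical fingerprint of a front-end configuration
#'
#' A canonical `key=value` string covering every stage parameter; two
#' configurations share a fingerprint exactly when all parameters are equal.
#' Stored on every feature matrix for reproducibility audits.
#'
#' @param config a [feature_config()].
#' @return a single character string.
#' @export
config_fingerprint <- function(config) {
  vals <- vapply(config, function(v) {
    if (is.null(v)) "default" else paste(format(v, digits = 17), collapse = ",")
  }, character(1))
  paste(sprintf("%s=%s", names(config), vals), collapse = ";")
}

dct_basis <- function(n_coeffs, k) {
  outer(seq_len(n_coeffs), seq_len(k),
        function(n, i) cos(n * (i - 0.5) * pi / k))
}

#' Cepstral coefficients from log band energies
#'
#' Per frame, `C_n = sum_{i=1..K} log10(S_i) * cos(n * (i - 1/2) * pi / K)`
#' for `n = 1..n_coeffs`. The index starts at 1, so the pure-DC term (n = 0)
#' is excluded; consequently a common multiplicative factor on all band
#' energies leaves every coefficient unchanged. Band energies are floored at
#' `log_floor` so the logarithm is always defined.
#'
#' @param bands an `n_frames x K` band-energy matrix (any nonnegative
#'   matrix works).
#' @param n_coeffs number of coefficients (must be <= K).
#' @param log_floor positive floor applied before `log10`.
#' @return an `n_frames x n_coeffs` matrix of class `cepstral_features`.
#' @export
log_dct_cepstrum <- function(bands, n_coeffs = 13, log_floor = 1e-12) {
  e <- unclass(bands)
  if (!is.matrix(e)) e <- matrix(e, nrow = 1L)
  k <- ncol(e)
  if (n_coeffs > k)
    stop(sprintf("n_coeffs (%d) must not exceed the number of bands (%d)",
                 n_coeffs, k))
  cc <- log10(pmax(e, log_floor)) %*% t(dct_basis(n_coeffs, k))
  colnames(cc) <- sprintf("C%d", seq_len(n_coeffs))
  structure(cc, class = c("cepstral_features", "matrix", "array"))
}

preemphasize <- function(signal, alpha) {
  if (alpha <= 0) return(signal)
  x <- signal$samples
  audio_signal(c(x[1L], x[-1L] - alpha * x[-length(x)]), signal$sample_rate)
}

fe_framing <- function(signal, config) {
  frame_signal(signal, config$frame_ms, config$hop_ms, config$window)
}

fe_nfft <- function(frames, config) {
  config$nfft %||% 2^ceiling(log2(frames$frame_length))
}

mel_bank_for <- function(config, sample_rate, nfft) {
  design_mel_filterbank(
    filterbank_spec("mel_triangular", n_filters = config$n_filters,
                    f_min = config$f_min, f_max = config$f_max,
                    sample_rate = sample_rate),
    nfft)
}

gammatone_bank_for <- function(config, sample_rate, nfft) {
  key <- paste("gtbank", sample_rate, nfft, config$n_filters, config$f_min,
               config$f_max %||% "nyq", config$erb_multiplier,
               config$gammatone_order, config$gammatone_b, sep = "|")
  bank <- .tecc_cache[[key]]
  if (is.null(bank)) {
    bank <- design_gammatone_bank(
      filterbank_spec("gammatone", n_filters = config$n_filters,
                      f_min = config$f_min, f_max = config$f_max,
                      bandwidth_multiplier = config$erb_multiplier,
                      order = config$gammatone_order, b = config$gammatone_b,
                      sample_rate = sample_rate),
      nfft)
    .tecc_cache[[key]] <- bank
  }
  bank
}

# filter a signal through every gammatone kernel by FFT convolution;
# returns an N x K matrix of band signals (causal, no delay compensation)
gammatone_band_signals <- function(signal, bank) {
  x <- signal$samples
  n <- length(x)
  lmax <- max(vapply(bank$impulse_responses, length, integer(1)))
  p <- 2^ceiling(log2(n + lmax))
  key <- paste("gtfft", p, paste(round(bank$center_frequencies, 6),
                                 collapse = ","),
               bank$spec$sample_rate, bank$spec$bandwidth_multiplier,
               bank$spec$order, bank$spec$b, sep = "|")
  kfft <- .tecc_cache[[key]]
  if (is.null(kfft)) {
    kfft <- lapply(bank$impulse_responses, function(kern)
      stats::fft(c(kern, numeric(p - length(kern)))))
    .tecc_cache[[key]] <- kfft
  }
  xf <- stats::fft(c(x, numeric(p - n)))
  vapply(kfft, function(hf)
    Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(n)] / p,
    numeric(n))
}

new_cepstral_features <- function(cc, kind, config) {
  structure(unclass(cc), class = c("cepstral_features", "matrix", "array"),
            feature_kind = kind, config_fingerprint = config_fingerprint(config))
}

#' @export
print.cepstral_features <- function(x, ...) {
  cat(sprintf("<cepstral_features> %s: %d frames x %d coefficients\n",
              attr(x, "feature_kind") %||% "?", nrow(x), ncol(x)))
  invisible(x)
}

#' Cepstral front-ends: MFCC, MTECC and GTECC
#'
#' Three waveform-to-cepstrum pipelines sharing the framing, log and DCT
#' stages:
#' \describe{
#'   \item{MFCC}{frame -> FFT magnitude -> Mel triangular bank -> log10 ->
#'     DCT.}
#'   \item{MTECC}{as MFCC, with the absolute Teager energy operator applied
#'     across the Mel band axis of each frame between the filter bank and the
#'     log.}
#'   \item{GTECC}{gammatone filter bank (Bark-spaced centers, `F * ERB(fc)`
#'     bandwidths). In the default `teo_mode = "temporal"` the Teager
#'     operator runs along each time-domain band signal and `|psi|` is
#'     averaged per analysis frame; in `"spectral"` mode the operator runs
#'     across the band axis of each frame's spectral band energies.}
#' }
#' All three return the first `n_coeffs` (default 13) coefficients of the
#' log10/DCT cepstrum per frame.
#'
#' @param signal an [audio_signal].
#' @param config a [feature_config()].
#' @return an `n_frames x n_coeffs` matrix of class `cepstral_features` with
#'   attributes `feature_kind` and `config_fingerprint`.
#' @examples
#' v <- synthesize_voice(voice_spec(duration = 0.2))
#' dim(extract_mfcc(v))
#' @export
extract_mfcc <- function(signal, config = feature_config()) {
  signal <- preemphasize(as_audio_signal(signal), config$preemphasis)
  fm <- fe_framing(signal, config)
  nfft <- fe_nfft(fm, config)
  sp <- stft_magnitude(fm, nfft)
  be <- apply_filterbank(sp, mel_bank_for(config, signal$sample_rate, nfft),
                         config$band_energy)
  new_cepstral_features(log_dct_cepstrum(be, config$n_coeffs,
                                         config$log_floor),
                        "MFCC", config)
}

#' @rdname extract_mfcc
#' @export
extract_mtecc <- function(signal, config = feature_config()) {
  signal <- preemphasize(as_audio_signal(signal), config$preemphasis)
  fm <- fe_framing(signal, config)
  nfft <- fe_nfft(fm, config)
  sp <- stft_magnitude(fm, nfft)
  be <- apply_filterbank(sp, mel_bank_for(config, signal$sample_rate, nfft),
                         config$band_energy)
  te <- teo_band_energies(be, mode = "spectral")
  new_cepstral_features(log_dct_cepstrum(te, config$n_coeffs,
                                         config$log_floor),
                        "MTECC", config)
}

#' @rdname extract_mfcc
#' @export
extract_gtecc <- function(signal, config = feature_config()) {
  signal <- preemphasize(as_audio_signal(signal), config$preemphasis)
  fm <- fe_framing(signal, config)
  nfft <- fe_nfft(fm, config)
  bank <- gammatone_bank_for(config, signal$sample_rate, nfft)
  te <- if (config$teo_mode == "temporal") {
    bs <- gammatone_band_signals(signal, bank)
    teo_band_energies(bs, mode = "temporal",
                      frame_length = fm$frame_length, hop = fm$hop)
  } else {
    sp <- stft_magnitude(fm, nfft)
    be <- apply_filterbank(sp, bank, config$band_energy)
    teo_band_energies(be, mode = "spectral")
  }
  new_cepstral_features(log_dct_cepstrum(te, config$n_coeffs,
                                         config$log_floor),
                        "GTECC", config)
}

#' Extract features by kind
#'
#' @param signal an [audio_signal].
#' @param kind `"mfcc"`, `"mtecc"` or `"gtecc"` (case-insensitive).
#' @param config a [feature_config()].
#' @return a `cepstral_features` matrix.
#' @export
extract_features <- function(signal, kind, config = feature_config()) {
  switch(tolower(kind),
         mfcc = extract_mfcc(signal, config),
         mtecc = extract_mtecc(signal, config),
         gtecc = extract_gtecc(signal, config),
         stop("unknown feature kind: ", kind))
}

#' Pool frame-level features into one utterance vector
#'
#' Per-coefficient mean (default) or median over frames. This is how a
#' variable-length utterance becomes the fixed 13-dimensional input of the
#' classifier.
#'
#' @param features a `cepstral_features` matrix (>= 1 frame).
#' @param method `"mean"` or `"median"`.
#' @return a named numeric vector of length `ncol(features)`.
#' @export
pool_utterance <- function(features, method = c("mean", "median")) {
  method <- match.arg(method)
  m <- unclass(features)
  if (!is.matrix(m) || nrow(m) < 1L) stop("features must have at least one frame")
  out <- if (method == "mean") colMeans(m) else apply(m, 2L, stats::median)
  names(out) <- colnames(m)
  out
}

#' Pooled feature matrix for a dataset
#'
#' @param dataset a `voice_dataset` (list of items with `signal`).
#' @param kind feature kind (see [extract_features()]).
#' @param config a [feature_config()].
#' @return an `n_utterances x n_coeffs` numeric matrix.
#' @export
pooled_feature_matrix <- function(dataset, kind, config = feature_config()) {
  t(vapply(dataset, function(it) {
    pool_utterance(extract_features(it$signal, kind, config),
                   method = config$pooling)
  }, numeric(config$n_coeffs)))
}

#' Write pooled features to CSV
#'
#' One row per utterance: `id`, `label`, `feature_kind`, then `C1..Cn`.
#'
#' @param dataset a `voice_dataset`.
#' @param kind feature kind.
#' @param path output CSV path.
#' @param config a [feature_config()].
#' @return the data frame written, invisibly.
#' @export
write_feature_csv <- function(dataset, kind, path,
                              config = feature_config()) {
  x <- pooled_feature_matrix(dataset, kind, config)
  df <- data.frame(id = seq_len(nrow(x)), label = dataset_labels(dataset),
                   feature_kind = toupper(kind))
  df <- cbind(df, as.data.frame(x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
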