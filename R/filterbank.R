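#' Auditory frequency scales
#'
#' `mel_scale()` maps Hz to mel, `2595 * log10(1 + f / 700)`; `mel_to_hz()`
#' is its inverse. `erb_hz()` is the equivalent rectangular bandwidth of the
#' auditory filter centered at `f_hz`,
#' `6.23 * (f/1000)^2 + 93.39 * (f/1000) + 28.52` Hz. `bark_scale()` maps Hz
#' to the critical-band Bark scale, `26.81 * f / (f + 3920) - 0.53`;
#' `bark_to_hz()` is its inverse.
#'
#' @param f_hz frequency in Hz (vectorized, must be >= 0).
#' @param mel,bark values on the respective scales.
#' @return numeric vector on the target scale.
#' @examples
#' mel_scale(700)    # 2595 * log10(2)
#' erb_hz(1000)      # 128.14
#' bark_scale(3920)  # 26.81 / 2 - 0.53
#' @export
mel_scale <- function(f_hz) {
  check_nonneg_freq(f_hz)
  2595 * log10(1 + f_hz / 700)
}

#' @rdname mel_scale
#' @export
mel_to_hz <- function(mel) {
  700 * (10^(mel / 2595) - 1)
}

#' @rdname mel_scale
#' @export
erb_hz <- function(f_hz) {
  check_nonneg_freq(f_hz)
  6.23 * (f_hz / 1000)^2 + 93.39 * (f_hz / 1000) + 28.52
}

#' @rdname mel_scale
#' @export
bark_scale <- function(f_hz) {
  check_nonneg_freq(f_hz)
  26.81 * f_hz / (f_hz + 3920) - 0.53
}

#' @rdname mel_scale
#' @export
bark_to_hz <- function(bark) {
  if (any(bark + 0.53 >= 26.81))
    stop("bark value beyond the scale's asymptote (26.28)")
  3920 * (bark + 0.53) / (26.81 - (bark + 0.53))
}

check_nonneg_freq <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0))
    stop("frequency must be finite and >= 0 Hz", call. = FALSE)
  invisible(f)
}

#' Filter bank design specification
#'
#' @param kind `"mel_triangular"` or `"gammatone"`.
#' @param n_filters number of filters K (>= 2). The default 30 together with
#'   `bandwidth_multiplier = 1.5` is the configuration reported to work best
#'   for robust recognition with gammatone banks.
#' @param f_min,f_max band edges in Hz; must satisfy
#'   `0 <= f_min < f_max <= sample_rate / 2`. `f_max` defaults to Nyquist.
#' @param bandwidth_multiplier dimensionless multiplier F applied to
#'   `erb_hz(fc)` (gammatone only).
#' @param order gammatone filter order n (default 4).
#' @param b gammatone bandwidth coefficient (default 1.019).
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(kind = c("mel_triangular", "gammatone"),
                            n_filters = 30, f_min = 50, f_max = NULL,
                            bandwidth_multiplier = 1.5, order = 4, b = 1.019,
                            sample_rate = 16000) {
  kind <- match.arg(kind)
  if (is.null(f_max)) f_max <- sample_rate / 2
  if (!(f_min >= 0 && f_min < f_max && f_max <= sample_rate / 2))
    stop("band edges must satisfy 0 <= f_min < f_max <= sample_rate/2")
  if (n_filters < 2) stop("n_filters must be >= 2")
  if (bandwidth_multiplier <= 0) stop("bandwidth_multiplier must be > 0")
  if (order < 1) stop("order must be >= 1")
  structure(list(kind = kind, n_filters = as.integer(n_filters),
                 f_min = f_min, f_max = f_max,
                 bandwidth_multiplier = bandwidth_multiplier,
                 order = as.integer(order), b = b,
                 sample_rate = sample_rate),
            class = "filterbank_spec")
}

new_filterbank_response <- function(kind, centers, weights, bandwidths,
                                    spec, nfft, freqs,
                                    impulse_responses = NULL) {
  structure(list(kind = kind, center_frequencies = centers, weights = weights,
                 bandwidths = bandwidths, spec = spec, nfft = nfft,
                 freqs = freqs, impulse_responses = impulse_responses),
            class = "filterbank_response")
}

#' @export
print.filterbank_response <- function(x, ...) {
  cat(sprintf("<filterbank_response> %s, %d filters, centers %.0f-%.0f Hz, nfft %d\n",
              x$kind, length(x$center_frequencies),
              min(x$center_frequencies), max(x$center_frequencies), x$nfft))
  invisible(x)
}

#' Design a Mel-scale triangular filter bank
#'
#' K triangles with peak weight 1, centers equally spaced on the mel axis
#' between `mel_scale(f_min)` and `mel_scale(f_max)`; each triangle rises from
#' the previous center and falls to zero exactly at the next (the K + 2
#' support points are the mel-equispaced grid).
#'
#' @param spec a [filterbank_spec()] with `kind = "mel_triangular"`.
#' @param nfft FFT length defining the spectral grid the weights are sampled
#'   on.
#' @return a `filterbank_response` with fields `center_frequencies`,
#'   `weights` (`K x (nfft/2 + 1)`), `bandwidths` (triangle base widths, Hz).
#' @export
design_mel_filterbank <- function(spec, nfft) {
  stopifnot(inherits(spec, "filterbank_spec"))
  if (spec$kind != "mel_triangular")
    stop("spec$kind must be 'mel_triangular'")
  k <- spec$n_filters
  edges_hz <- mel_to_hz(seq(mel_scale(spec$f_min), mel_scale(spec$f_max),
                            length.out = k + 2L))
  freqs <- (0:(nfft %/% 2L)) * spec$sample_rate / nfft
  weights <- matrix(0, nrow = k, ncol = length(freqs))
  for (j in seq_len(k)) {
    lo <- edges_hz[j]; ce <- edges_hz[j + 1L]; hi <- edges_hz[j + 2L]
    weights[j, ] <- pmax(0, pmin((freqs - lo) / (ce - lo),
                                 (hi - freqs) / (hi - ce)))
  }
  if (any(rowSums(weights > 0) == 0))
    stop("some triangles have no support on the nfft grid; ",
         "increase nfft or reduce n_filters")
  new_filterbank_response("mel_triangular", edges_hz[2:(k + 1L)], weights,
                          bandwidths = edges_hz[3:(k + 2L)] - edges_hz[1:k],
                          spec = spec, nfft = nfft, freqs = freqs)
}

#' Gammatone filter impulse response
#'
#' `g(t) = A * t^(n-1) * exp(-2*pi*b*F*ERB(fc)*t) * cos(2*pi*fc*t)` sampled at
#' `spec$sample_rate`, with the gain A chosen so that the magnitude of the
#' discrete-time frequency response at `fc` is exactly 1.
#'
#' @param f_c center frequency in Hz, inside `(0, sample_rate/2)`.
#' @param spec a [filterbank_spec()] with `kind = "gammatone"` (supplies
#'   `order`, `b`, `bandwidth_multiplier`, `sample_rate`).
#' @param length kernel length in samples. Default: long enough to contain
#'   99.9% of the envelope energy. An explicit length holding less than 99%
#'   is an error.
#' @return numeric kernel of the requested length.
#' @export
gammatone_impulse_response <- function(f_c, spec, length = NULL) {
  stopifnot(inherits(spec, "filterbank_spec"))
  fs <- spec$sample_rate
  if (!(f_c > 0 && f_c < fs / 2))
    stop("f_c must lie strictly inside (0, sample_rate/2)")
  beta <- 2 * pi * spec$b * spec$bandwidth_multiplier * erb_hz(f_c)
  shape <- 2L * spec$order - 1L      # envelope energy t^(2n-2) e^(-2 beta t)
  if (is.null(length)) {
    # essentially the full envelope: truncating earlier (e.g. at 99.9%
    # energy) measurably widens the realized ERB through spectral leakage
    length <- max(32L, as.integer(ceiling(fs * qgamma(1 - 1e-8, shape,
                                                      rate = 2 * beta))))
  } else {
    length <- as.integer(length)
    if (pgamma(length / fs, shape, rate = 2 * beta) < 0.99)
      stop("kernel too short: holds < 99% of the gammatone envelope energy")
  }
  t <- (seq_len(length) - 1) / fs
  g0 <- t^(spec$order - 1) * exp(-beta * t) * cos(2 * pi * f_c * t)
  h_fc <- sum(g0 * exp(-2i * pi * f_c * t))
  a <- 1 / Mod(h_fc)
  a * g0
}

# sample the DTFT of a kernel on the nfft bin grid by time-aliasing the
# kernel into nfft samples, then one FFT
sample_dtft_on_grid <- function(kernel, nfft) {
  nb <- ceiling(length(kernel) / nfft)
  padded <- c(kernel, numeric(nb * nfft - length(kernel)))
  folded <- rowSums(matrix(padded, nrow = nfft))
  stats::fft(folded)[seq_len(nfft %/% 2L + 1L)]
}

# center placement margins, in units of the envelope decay half-width
# B = b * F * ERB(fc): the top filter must fit its passband below Nyquist
# and the bottom filter must clear DC, otherwise the realized (truncated)
# response cannot match the ERB(f) design bandwidth.
.gt_margin_hi <- 1.6
.gt_margin_lo <- 2.0

gammatone_center_range <- function(spec) {
  bf <- spec$b * spec$bandwidth_multiplier
  f_hi <- uniroot(function(f) f + .gt_margin_hi * bf * erb_hz(f) - spec$f_max,
                  lower = 1e-6, upper = spec$f_max, tol = 1e-9)$root
  f_lo_min <- uniroot(function(f) f - .gt_margin_lo * bf * erb_hz(f),
                      lower = 1e-6, upper = spec$sample_rate / 2,
                      tol = 1e-9)$root
  f_lo <- max(spec$f_min, f_lo_min)
  if (f_lo >= f_hi)
    stop("band [f_min, f_max] too narrow for a gammatone bank at this ",
         "sample rate")
  c(f_lo, f_hi)
}

#' Design a Gammatone auditory filter bank
#'
#' K center frequencies placed equidistantly on the Bark axis; each filter has
#' design bandwidth `F * erb_hz(fc)` and order-`n` gammatone shape. Spectral
#' weights are the squared magnitude of the sampled impulse response's
#' discrete-time frequency response on the `nfft` bin grid, peak-normalized
#' per filter. Centers are kept `1.6` (top) and `1.0` (bottom) decay
#' half-widths clear of the band edges so every realized filter can attain
#' its design ERB.
#'
#' @param spec a [filterbank_spec()] with `kind = "gammatone"`.
#' @param nfft FFT length defining the spectral grid.
#' @return a `filterbank_response`; `impulse_responses` holds the K kernels,
#'   `bandwidths` the design values `F * erb_hz(fc)` in Hz.
#' @export
design_gammatone_bank <- function(spec, nfft) {
  stopifnot(inherits(spec, "filterbank_spec"))
  if (spec$kind != "gammatone") stop("spec$kind must be 'gammatone'")
  if (spec$f_max > spec$sample_rate / 2)
    stop("f_max must not exceed sample_rate/2")
  rng <- gammatone_center_range(spec)
  zgrid <- seq(bark_scale(rng[1]), bark_scale(rng[2]),
               length.out = spec$n_filters)
  centers <- bark_to_hz(zgrid)
  kernels <- lapply(centers, gammatone_impulse_response, spec = spec)
  nb <- nfft %/% 2L + 1L
  weights <- t(vapply(kernels, function(kern) {
    p <- Mod(sample_dtft_on_grid(kern, nfft))^2
    p / max(p)
  }, numeric(nb)))
  new_filterbank_response("gammatone", centers, weights,
                          bandwidths = spec$bandwidth_multiplier *
                            erb_hz(centers),
                          spec = spec, nfft = nfft,
                          freqs = (0:(nfft %/% 2L)) * spec$sample_rate / nfft,
                          impulse_responses = kernels)
}

#' Numerically measured equivalent rectangular bandwidth of a kernel
#'
#' Evaluates the kernel's power response on a dense DFT grid and returns
#' `sum(|H|^2) * df / max(|H|^2)` over `[0, Nyquist]` — the bandwidth of the
#' ideal rectangular filter with the same peak gain and energy.
#'
#' @param kernel time-domain filter kernel.
#' @param sample_rate sampling rate in Hz.
#' @param nfft_dense dense grid size (default `2^16`).
#' @return measured ERB in Hz.
#' @export
measured_erb <- function(kernel, sample_rate, nfft_dense = 2^16) {
  if (length(kernel) > nfft_dense)
    nfft_dense <- 2^ceiling(log2(length(kernel)))
  h <- stats::fft(c(kernel, numeric(nfft_dense - length(kernel))))
  p <- Mod(h[seq_len(nfft_dense %/% 2L + 1L)])^2
  sum(p) * (sample_rate / nfft_dense) / max(p)
}

#' Accumulate a spectrum into per-band energies
#'
#' Per frame and band, the weighted sum over FFT bins of the squared
#' (`band_energy = "power"`, default) or plain (`"magnitude"`) magnitude
#' spectrum.
#'
#' @param spectrum an [stft_magnitude()] result.
#' @param bank a `filterbank_response` whose weight columns match the
#'   spectrum's bins.
#' @param band_energy `"power"` or `"magnitude"`.
#' @return an `n_frames x K` matrix of class `band_energies` (attributes:
#'   `kind`, `center_frequencies`, `sample_rate`).
#' @export
apply_filterbank <- function(spectrum, bank,
                             band_energy = c("power", "magnitude")) {
  stopifnot(inherits(spectrum, "stft_spectrum"),
            inherits(bank, "filterbank_response"))
  band_energy <- match.arg(band_energy)
  if (ncol(bank$weights) != ncol(spectrum$magnitudes))
    stop(sprintf("filter bank has %d bins but spectrum has %d",
                 ncol(bank$weights), ncol(spectrum$magnitudes)))
  s <- spectrum$magnitudes
  if (band_energy == "power") s <- s^2
  e <- s %*% t(bank$weights)
  structure(e, class = c("band_energies", class(e)),
            kind = bank$kind, center_frequencies = bank$center_frequencies,
            sample_rate = spectrum$sample_rate)
}

#' Export / import a filter bank as CSV
#'
#' One row per filter: center frequency, design bandwidth, then the spectral
#' weights. Intended for golden-file comparisons.
#'
#' @param bank a `filterbank_response`.
#' @param path CSV path.
#' @return `export_filterbank()`: `path` invisibly; `import_filterbank()`:
#'   a list with `center_frequencies`, `bandwidths`, `weights`.
#' @export
export_filterbank <- function(bank, path) {
  df <- data.frame(center_hz = bank$center_frequencies,
                   bandwidth_hz = bank$bandwidths)
  w <- as.data.frame(bank$weights)
  names(w) <- sprintf("w%04d", seq_len(ncol(w)))
  utils::write.csv(cbind(df, w), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_filterbank
#' @export
import_filterbank <- function(path) {
  df <- utils::read.csv(path)
  list(center_frequencies = df$center_hz, bandwidths = df$bandwidth_hz,
       weights = as.matrix(df[, grep("^w", names(df)), drop = FALSE]))
}
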