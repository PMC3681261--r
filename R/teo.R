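#' Discrete Teager-Kaiser energy operator
#'
#' `psi[n] = q[n]^2 - q[n+1] * q[n-1]` at interior samples. For a sampled
#' oscillation `Q * cos(Omega * n + phi)` this equals `Q^2 * sin(Omega)^2`
#' exactly — an energy proportional to (amplitude x frequency)^2, the "true"
#' source energy of a resonance, rather than the mean-square amplitude. The
#' output may be negative pointwise for non-sinusoidal input.
#'
#' Boundary policy: the first and last samples replicate their nearest
#' interior value, keeping the output length equal to the input length. The
#' interior index range is recorded in attribute `valid_range`.
#'
#' @param q numeric sequence, length >= 3.
#' @return numeric vector of the same length with attribute `valid_range`
#'   (the 1-based interior index interval).
#' @examples
#' teager(1:10)          # a linear ramp has constant Teager energy 1
#' teager(cos(0.3 * (0:20)))
#' @export
teager <- function(q) {
  n <- length(q)
  if (n < 3L) stop("teager requires at least 3 samples")
  if (!is.numeric(q)) stop("q must be numeric")
  psi <- numeric(n)
  psi[2:(n - 1L)] <- q[2:(n - 1L)]^2 - q[3:n] * q[1:(n - 2L)]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  attr(psi, "valid_range") <- c(2L, n - 1L)
  psi
}

#' Teager energy of band decompositions
#'
#' Applies the discrete Teager-Kaiser operator to a band decomposition and
#' takes absolute values, guaranteeing nonnegative energies ahead of the log
#' stage.
#'
#' Two input forms are accepted:
#' \describe{
#'   \item{time-domain band signals}{a plain `N x K` matrix of filtered
#'     waveforms (one column per band, e.g. gammatone outputs). Only
#'     `mode = "temporal"` applies: the operator runs along time within each
#'     band, then `|psi|` is averaged over analysis frames of `frame_length`
#'     samples every `hop` samples, yielding an `n_frames x K` matrix.}
#'   \item{frame-domain band energies}{a `band_energies` matrix from
#'     [apply_filterbank()]. `mode = "spectral"` applies the operator across
#'     the band (frequency) axis within each frame; `mode = "temporal"` along
#'     each band's frame-time trajectory.}
#' }
#'
#' @param x band signals or band energies (see Details).
#' @param mode `"temporal"` or `"spectral"`.
#' @param frame_length,hop framing parameters in samples (time-domain band
#'   signals only).
#' @return an `n_frames x K` matrix of class `band_energies`, all entries
#'   >= 0.
#' @export
teo_band_energies <- function(x, mode = c("temporal", "spectral"),
                              frame_length = NULL, hop = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "band_energies")) {
    e <- unclass(x)
    if (mode == "temporal") {
      if (nrow(e) < 3L)
        stop("temporal mode needs at least 3 frames per band")
      out <- apply(e, 2L, function(col) abs(teager(col)))
    } else {
      if (ncol(e) < 3L)
        stop("spectral mode needs at least 3 bands per frame")
      out <- t(apply(e, 1L, function(row) abs(teager(row))))
    }
    attrs <- attributes(x)
    structure(out, class = c("band_energies", "matrix", "array"),
              kind = attrs$kind, center_frequencies = attrs$center_frequencies,
              sample_rate = attrs$sample_rate)
  } else if (is.matrix(x)) {
    if (mode != "temporal")
      stop("unknown mode for time-domain band signals: use 'temporal'")
    if (is.null(frame_length) || is.null(hop))
      stop("frame_length and hop are required for time-domain band signals")
    if (nrow(x) < max(3L, frame_length))
      stop("band signals shorter than one frame")
    e <- apply(x, 2L, function(col) abs(teager(col)))
    if (!is.matrix(e)) e <- matrix(e, ncol = ncol(x))
    starts <- seq.int(0L, nrow(x) - frame_length, by = hop)
    pooled <- vapply(starts, function(s) {
      colMeans(e[(s + 1L):(s + frame_length), , drop = FALSE])
    }, numeric(ncol(x)))
    out <- if (is.matrix(pooled)) t(pooled) else matrix(pooled, ncol = 1L)
    structure(out, class = c("band_energies", "matrix", "array"))
  } else {
    stop("x must be a band-signal matrix or a band_energies matrix")
  }
}
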