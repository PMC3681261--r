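#' Audio signal container
#'
#' A minimal container for a mono, uniformly sampled waveform. All feature
#' extractors and the synthesis module exchange this type.
#'
#' @param samples numeric vector of dimensionless amplitudes, nominally in
#'   \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `audio_signal`: a list with elements `samples`
#'   and `sample_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' x
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_field("samples", "must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop_field("samples", "contains non-finite values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0)
    stop_field("sample_rate", "must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

as_audio_signal <- function(x, sample_rate = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(sample_rate))
    stop("a raw numeric vector needs an explicit sample_rate", call. = FALSE)
  audio_signal(x, sample_rate)
}
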