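#' Read a mono PCM WAV file
#'
#' Supports uncompressed 16-bit integer PCM and 32-bit IEEE float mono files.
#' Multichannel input is rejected (all analysis in this package is mono).
#'
#' @param path file path.
#' @return an [audio_signal].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw_fmt[1:2], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        channels = readBin(raw_fmt[3:4], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        rate     = readBin(raw_fmt[5:8], "integer", 1L, size = 4L,
                           endian = "little"),
        bits     = readBin(raw_fmt[15:16], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L)
        stop("multichannel WAV not supported (", fmt$channels, " channels)")
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                           endian = "little") / 32767
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        samples <- readBin(con, "double", n, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit)")
      }
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_signal(samples, fmt$rate)
}

#' Write a mono PCM WAV file
#'
#' @param signal an [audio_signal]; amplitudes outside \[-1, 1\] are clipped.
#' @param path output path.
#' @param bit_depth 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  signal <- as_audio_signal(signal)
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32")
  x <- signal$samples
  fs <- as.integer(round(signal$sample_rate))
  n <- length(x)
  bytes_per <- bit_depth %/% 8L
  data_bytes <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  fmt_code <- if (bit_depth == 16) 1L else 3L
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  if (bit_depth == 16) {
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
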