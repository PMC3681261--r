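#' Specification of a synthetic voice
#'
#' Parameters of the source-filter voice model used to emulate sustained
#' vowels from normophonic and dysphonic speakers. The source is a glottal
#' pulse train (Rosenberg pulse shape) whose cycle-to-cycle period and
#' amplitude are perturbed by jitter and shimmer, mixed with white aspiration
#' noise at a controlled harmonic-to-noise power ratio, then filtered through
#' second-order formant resonators.
#'
#' Jitter and shimmer are applied as per-cycle multiplicative Gaussian
#' perturbations with standard deviation `jitter_pct/100` (resp.
#' `shimmer_pct/100`), truncated at three standard deviations — the usual
#' dysphonia-simulation convention.
#'
#' @param f0 fundamental frequency in Hz.
#' @param duration signal duration in seconds.
#' @param jitter_pct cycle-to-cycle period perturbation, percent of the period.
#' @param shimmer_pct cycle-to-cycle amplitude perturbation, percent.
#' @param aspiration_snr_db harmonic-to-aspiration-noise power ratio in dB;
#'   lower values give breathier, noisier voices.
#' @param formants list of `c(center_hz, bandwidth_hz)` vocal-tract resonances;
#'   the default approximates the vowel /a/.
#' @param sample_rate sampling rate in Hz; must be at least twice the highest
#'   formant center.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `voice_spec`.
#' @export
voice_spec <- function(f0 = 120, duration = 0.5, jitter_pct = 0,
                       shimmer_pct = 0, aspiration_snr_db = 30,
                       formants = list(c(730, 90), c(1090, 110),
                                       c(2440, 120), c(3400, 150)),
                       sample_rate = 16000, seed = 1L) {
  spec <- structure(list(f0 = f0, duration = duration,
                         jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                         aspiration_snr_db = aspiration_snr_db,
                         formants = formants, sample_rate = sample_rate,
                         seed = as.integer(seed)),
                    class = "voice_spec")
  validate_voice_spec(spec)
  spec
}

validate_voice_spec <- function(spec) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(spec$f0) || spec$f0 <= 0)
    stop_field("f0", "must be a single positive number (Hz)")
  if (!num1(spec$duration) || spec$duration <= 0)
    stop_field("duration", "must be a single positive number (seconds)")
  if (!num1(spec$jitter_pct) || spec$jitter_pct < 0)
    stop_field("jitter_pct", "must be >= 0")
  if (!num1(spec$shimmer_pct) || spec$shimmer_pct < 0)
    stop_field("shimmer_pct", "must be >= 0")
  if (!num1(spec$aspiration_snr_db))
    stop_field("aspiration_snr_db", "must be a single finite number (dB)")
  if (!num1(spec$sample_rate) || spec$sample_rate <= 0)
    stop_field("sample_rate", "must be a single positive number (Hz)")
  if (!is.list(spec$formants) || length(spec$formants) < 1L ||
      !all(vapply(spec$formants,
                  function(f) is.numeric(f) && length(f) == 2L &&
                    all(is.finite(f)) && all(f > 0), logical(1))))
    stop_field("formants", "must be a list of c(center_hz, bandwidth_hz) pairs")
  fmax <- max(vapply(spec$formants, `[`, numeric(1), 1L))
  if (spec$sample_rate < 2 * fmax)
    stop_field("sample_rate",
               sprintf("must be >= twice the highest formant center (%g Hz)",
                       fmax))
  if (!num1(spec$seed))
    stop_field("seed", "must be a single integer")
  invisible(spec)
}

# Rosenberg glottal pulse sampled over one cycle of `len` samples:
# raised-cosine opening over 40% of the cycle, cosine-quarter closing over
# 16%, closed phase for the remainder.
rosenberg_pulse <- function(len) {
  n1 <- max(1L, as.integer(round(0.40 * len)))
  n2 <- max(1L, as.integer(round(0.16 * len)))
  if (n1 + n2 > len) n2 <- max(0L, len - n1)
  opening <- 0.5 * (1 - cos(pi * (seq_len(n1) - 1) / n1))
  closing <- if (n2 > 0) cos(pi * (seq_len(n2) - 1) / (2 * n2)) else numeric(0)
  c(opening, closing, numeric(len - n1 - n2))
}

# second-order all-pole resonator at center f, bandwidth bw
resonator <- function(x, f, bw, fs) {
  r <- exp(-pi * bw / fs)
  th <- 2 * pi * f / fs
  g <- 1 - 2 * r * cos(th) + r^2
  as.numeric(stats::filter(g * x, c(2 * r * cos(th), -r^2),
                           method = "recursive"))
}

#' Synthesize a voice signal from a spec
#'
#' Source-filter synthesis: glottal pulse train at `f0` with per-cycle period
#' jitter and amplitude shimmer, white aspiration noise mixed at
#' `aspiration_snr_db`, formant filtering, then peak normalization to unit
#' maximum amplitude. Deterministic under `spec$seed`.
#'
#' @param spec a [voice_spec].
#' @return an [audio_signal] with `max(abs(samples)) == 1`.
#' @examples
#' v <- synthesize_voice(voice_spec(f0 = 150, duration = 0.3, seed = 2))
#' v
#' @export
synthesize_voice <- function(spec) {
  validate_voice_spec(spec)
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration * fs))
  t0 <- fs / spec$f0                       # nominal period, samples
  sj <- spec$jitter_pct / 100
  ss <- spec$shimmer_pct / 100

  withr::with_seed(spec$seed, {
    pulses <- list()
    total <- 0L
    pos <- 0                               # fractional cycle boundary
    while (total < n) {
      eps <- if (sj > 0) max(-3 * sj, min(3 * sj, rnorm(1, 0, sj))) else 0
      eta <- if (ss > 0) max(-3 * ss, min(3 * ss, rnorm(1, 0, ss))) else 0
      nxt <- pos + t0 * (1 + eps)
      len <- max(8L, as.integer(round(nxt) - round(pos)))
      pulses[[length(pulses) + 1L]] <- (1 + eta) * rosenberg_pulse(len)
      total <- total + len
      pos <- nxt
    }
    src <- unlist(pulses, use.names = FALSE)[seq_len(n)]

    w <- rnorm(n)
    gain <- sqrt(mean(src^2) / (mean(w^2) * 10^(spec$aspiration_snr_db / 10)))
    x <- src + gain * w
    for (fm in spec$formants) x <- resonator(x, fm[1L], fm[2L], fs)
    audio_signal(x / max(abs(x)), fs)
  })
}

#' Default perturbation ranges for the two voice classes
#'
#' Normal voices: low jitter (< 1%), low shimmer (< 3%), weak aspiration noise
#' (harmonic-to-noise ratio above 25 dB). Pathological voices: elevated jitter
#' (2-8%), shimmer (5-20%) and aspiration noise (5-15 dB), the perturbation
#' regime reported for dysphonic phonation.
#'
#' @return a named list of `c(min, max)` ranges for `f0`, `jitter_pct`,
#'   `shimmer_pct` and `aspiration_snr_db`.
#' @export
normal_voice_ranges <- function() {
  list(f0 = c(100, 220), jitter_pct = c(0.05, 1), shimmer_pct = c(0.5, 3),
       aspiration_snr_db = c(25, 40))
}

#' @rdname normal_voice_ranges
#' @export
pathological_voice_ranges <- function() {
  list(f0 = c(90, 230), jitter_pct = c(2, 8), shimmer_pct = c(5, 20),
       aspiration_snr_db = c(5, 15))
}

draw_from_ranges <- function(ranges, n) {
  fields <- c("f0", "jitter_pct", "shimmer_pct", "aspiration_snr_db")
  miss <- setdiff(fields, names(ranges))
  if (length(miss))
    stop("parameter ranges missing fields: ", paste(miss, collapse = ", "))
  out <- lapply(ranges[fields], function(r) {
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2])
      stop("each range must be c(min, max) with min <= max")
    runif(n, r[1], r[2])
  })
  names(out) <- fields
  out
}

ranges_overlap <- function(a, b) {
  any(vapply(c("jitter_pct", "shimmer_pct"), function(f) {
    a[[f]][2] >= b[[f]][1] && b[[f]][2] >= a[[f]][1]
  }, logical(1)))
}

#' Generate a labeled synthetic voice dataset
#'
#' Draws per-voice parameters uniformly from the class ranges and synthesizes
#' each voice with a seed derived deterministically from `seed`, so the whole
#' dataset is bit-reproducible.
#'
#' @param n_normal,n_pathological number of voices per class (both > 0).
#' @param normal_ranges,pathological_ranges named lists of `c(min, max)`
#'   ranges (see [normal_voice_ranges()]).
#' @param seed integer master seed.
#' @param duration per-voice duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `voice_dataset`: a list of items, each a list
#'   with elements `signal` ([audio_signal]), `label` (`"normal"` or
#'   `"pathological"`) and `spec` ([voice_spec]).
#' @export
make_voice_dataset <- function(n_normal, n_pathological,
                               normal_ranges = normal_voice_ranges(),
                               pathological_ranges = pathological_voice_ranges(),
                               seed = 1L, duration = 0.5, sample_rate = 16000) {
  if (!is.numeric(n_normal) || n_normal < 1 ||
      !is.numeric(n_pathological) || n_pathological < 1)
    stop("n_normal and n_pathological must be positive counts")
  n_normal <- as.integer(n_normal)
  n_pathological <- as.integer(n_pathological)
  if (ranges_overlap(normal_ranges, pathological_ranges))
    warning("normal and pathological perturbation ranges overlap; ",
            "class separability is not guaranteed")

  params <- withr::with_seed(as.integer(seed), {
    list(normal = draw_from_ranges(normal_ranges, n_normal),
         pathological = draw_from_ranges(pathological_ranges, n_pathological))
  })

  item_seed <- function(i) as.integer((as.double(seed) * 7919 + i * 104729) %%
                                        2147483646 + 1)
  build <- function(class, idx_offset) {
    p <- params[[class]]
    lapply(seq_along(p$f0), function(i) {
      sp <- voice_spec(f0 = p$f0[i], duration = duration,
                       jitter_pct = p$jitter_pct[i],
                       shimmer_pct = p$shimmer_pct[i],
                       aspiration_snr_db = p$aspiration_snr_db[i],
                       sample_rate = sample_rate,
                       seed = item_seed(idx_offset + i))
      list(signal = synthesize_voice(sp), label = class, spec = sp)
    })
  }
  items <- c(build("normal", 0L), build("pathological", n_normal))
  structure(items, class = "voice_dataset",
            seed = as.integer(seed), duration = duration,
            sample_rate = sample_rate)
}

#' @export
print.voice_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat(sprintf("<voice_dataset> %d voices (%d normal, %d pathological) @ %g Hz\n",
              length(x), sum(lab == "normal"), sum(lab == "pathological"),
              attr(x, "sample_rate") %||% x[[1]]$signal$sample_rate))
  invisible(x)
}

#' Class labels of a voice dataset
#'
#' @param dataset a `voice_dataset` (or any list of items with a `label`).
#' @return character vector of labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(it) it$label, character(1))
}

#' Write a voice dataset to WAV files plus a CSV manifest
#'
#' @param dataset a `voice_dataset`.
#' @param dir output directory (created if absent).
#' @param bit_depth passed to [write_wav()].
#' @return path of the written manifest, invisibly.
#' @export
write_voice_dataset <- function(dataset, dir, bit_depth = 16) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    it <- dataset[[i]]
    fname <- sprintf("voice_%03d_%s.wav", i, it$label)
    write_wav(it$signal, file.path(dir, fname), bit_depth = bit_depth)
    data.frame(filename = fname, label = it$label, f0 = it$spec$f0,
               jitter_pct = it$spec$jitter_pct,
               shimmer_pct = it$spec$shimmer_pct,
               aspiration_snr_db = it$spec$aspiration_snr_db,
               seed = it$spec$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a voice dataset written by [write_voice_dataset()]
#'
#' @param dir directory containing WAV files and `manifest.csv`.
#' @return a `voice_dataset` (specs reduced to the manifest columns).
#' @export
read_voice_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(manifest)), function(i) {
    list(signal = read_wav(file.path(dir, manifest$filename[i])),
         label = manifest$label[i],
         spec = as.list(manifest[i, ]))
  })
  structure(items, class = "voice_dataset")
}
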