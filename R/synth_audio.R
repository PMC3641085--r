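#' Prosody profile for utterance synthesis
#'
#' A prosody profile describes the melodic and rhythmic envelope of a speech
#' style: its mean fundamental frequency (F0), the peak-to-trough excursion of
#' the intonation contour, and the syllable rate. Parentese (infant-directed
#' emotional prosody) is characterised by higher pitch, slower tempo and
#' exaggerated intonation contours than adult-directed speech, and the default
#' profiles encode exactly that contrast.
#'
#' @param mean_f0 Mean fundamental frequency in Hz (> 0).
#' @param f0_excursion Peak-to-trough F0 excursion of the intonation contour,
#'   in Hz (>= 0).
#' @param syllable_rate Syllable rate in syllables per second (> 0).
#' @param harmonics Number of harmonics in the synthetic glottal source.
#' @param snr_db Signal-to-noise ratio of the additive white noise, in dB.
#'
#' @return An object of class `prosody_profile` (a named list).
#' @examples
#' prosody_profile(mean_f0 = 350, f0_excursion = 200, syllable_rate = 2.5)
#' @export
prosody_profile <- function(mean_f0, f0_excursion, syllable_rate,
                            harmonics = 8L, snr_db = 25) {
  if (mean_f0 <= 0) abort("`mean_f0` must be positive.")
  if (f0_excursion < 0) abort("`f0_excursion` must be non-negative.")
  if (syllable_rate <= 0) abort("`syllable_rate` must be positive.")
  structure(
    list(
      mean_f0 = mean_f0, f0_excursion = f0_excursion,
      syllable_rate = syllable_rate, syllable_duration = 1 / syllable_rate,
      harmonics = as.integer(harmonics), snr_db = snr_db
    ),
    class = "prosody_profile"
  )
}

#' Default prosody profiles for the two speech styles
#'
#' Parentese: mean F0 350 Hz, excursion 200 Hz, 2.5 syllables/s.
#' Adult-directed: mean F0 210 Hz, excursion 60 Hz, 4.5 syllables/s.
#' The parentese profile dominates the adult-directed one on pitch height,
#' contour excursion and (inversely) tempo.
#'
#' @return Named list with elements `parentese` and `adult_directed`.
#' @export
default_profiles <- function() {
  list(
    parentese      = prosody_profile(350, 200, 2.5),
    adult_directed = prosody_profile(210, 60, 4.5)
  )
}

#' Synthesise a single labelled utterance
#'
#' Generates a harmonic-source waveform whose F0 follows a piecewise-smooth
#' random intonation contour drawn from the style's prosody profile, amplitude
#' modulated into syllable-like bursts, with additive white noise at the
#' profile's SNR. The ground-truth F0 contour is returned alongside the
#' waveform so downstream estimators can be checked against it. Deterministic
#' given `seed`.
#'
#' @param style `"parentese"` or `"adult_directed"`.
#' @param duration Duration in seconds, in `[0.5, 10]`.
#' @param seed Integer seed.
#' @param sample_rate Sample rate in Hz (default 16000).
#' @param profiles Named list of [prosody_profile()]s keyed by style.
#'
#' @return An object of class `utterance`: a list with `waveform` (numeric in
#'   `[-1, 1]`), `sample_rate`, `style`, `duration`, `profile`, and `f0_truth`,
#'   a tibble of the ground-truth contour sampled every 10 ms (`time`, `f0`,
#'   `voiced`).
#' @examples
#' u <- synth_utterance("parentese", duration = 1, seed = 1)
#' mean(u$f0_truth$f0[u$f0_truth$voiced])
#' @export
synth_utterance <- function(style = c("parentese", "adult_directed"),
                            duration = 2, seed = 1L, sample_rate = 16000,
                            profiles = default_profiles()) {
  style <- match.arg(style)
  if (!is.numeric(duration) || duration < 0.5 || duration > 10) {
    abort("`duration` must be in [0.5, 10] seconds.")
  }
  prof <- profiles[[style]]
  if (is.null(prof)) abort(paste0("no profile for style '", style, "'"))

  with_seed(seed, {
    n <- round(duration * sample_rate)
    t <- seq_len(n) / sample_rate

    # Intonation contour: two slow sinusoids with random phase and rate plus a
    # gentle random declination, scaled so peak-to-trough ~= f0_excursion.
    rates <- stats::runif(2, 0.4, 1.8)
    phases <- stats::runif(2, 0, 2 * pi)
    raw <- sin(2 * pi * rates[1] * t + phases[1]) +
      0.5 * sin(2 * pi * rates[2] * t + phases[2]) +
      stats::runif(1, -0.3, 0.3) * (t - duration / 2)
    raw <- raw - mean(raw)
    span <- max(raw) - min(raw)
    f0 <- prof$mean_f0 + if (span > 0) raw * (prof$f0_excursion / span) else 0
    f0 <- pmax(f0, 60)
    f0 <- f0 - mean(f0) + prof$mean_f0  # exact mean at the profile value

    # Syllabic amplitude envelope: raised-cosine bursts at the syllable rate,
    # random burst phase; squared to sharpen onsets, small floor keeps the
    # source continuous.
    syl_phase <- stats::runif(1, 0, 2 * pi)
    env <- (0.5 - 0.5 * cos(2 * pi * prof$syllable_rate * t + syl_phase))^2
    env <- 0.05 + 0.95 * env

    # Harmonic source with 1/h rolloff, capped below Nyquist.
    phase <- 2 * pi * cumsum(f0) / sample_rate
    wave <- numeric(n)
    for (h in seq_len(prof$harmonics)) {
      if (max(f0) * h >= sample_rate / 2) break
      wave <- wave + (1 / h) * sin(h * phase)
    }
    wave <- wave * env
    wave <- wave / max(abs(wave))

    # Additive white noise at the profile SNR.
    sig_pow <- mean(wave^2)
    noise_sd <- sqrt(sig_pow / 10^(prof$snr_db / 10))
    wave <- wave + stats::rnorm(n, sd = noise_sd)
    wave <- wave / max(abs(wave)) * 0.95

    hop <- 0.010
    ft <- seq(0, duration - hop, by = hop)
    f0_frame <- f0[pmin(n, round(ft * sample_rate) + 1L)]
    env_frame <- env[pmin(n, round(ft * sample_rate) + 1L)]

    structure(
      list(
        waveform = wave, sample_rate = sample_rate, style = style,
        duration = duration, profile = prof,
        f0_truth = tibble(time = ft, f0 = f0_frame, voiced = env_frame > 0.2)
      ),
      class = "utterance"
    )
  })
}

#' @export
print.utterance <- function(x, ...) {
  cat(sprintf(
    "<utterance> style=%s  %.2f s @ %d Hz  mean F0 (truth) = %.1f Hz\n",
    x$style, x$duration, x$sample_rate, mean(x$f0_truth$f0)
  ))
  invisible(x)
}

#' Synthesise a balanced labelled corpus
#'
#' Builds a balanced two-class corpus of synthetic utterances (parentese vs
#' adult-directed "other speech"), one row per utterance, with per-utterance
#' seeds derived from the master seed.
#'
#' @param n_per_class Utterances per class (>= 1).
#' @param seed Master integer seed.
#' @param duration_range Utterance durations are drawn uniformly from this
#'   range (seconds).
#' @param profiles As in [synth_utterance()].
#' @return A tibble with columns `id`, `style`, `seed`, `duration` and the
#'   list-column `utterance`.
#' @examples
#' corp <- synth_corpus(2, seed = 0)
#' table(corp$style)
#' @export
synth_corpus <- function(n_per_class, seed = 1L, duration_range = c(1, 3),
                         profiles = default_profiles()) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  n <- 2L * as.integer(n_per_class)
  seeds <- derive_seeds(seed, n)
  durations <- with_seed(seed + 1, stats::runif(n, duration_range[1], duration_range[2]))
  styles <- rep(c("parentese", "adult_directed"), each = n_per_class)
  tibble(
    id = sprintf("utt%03d", seq_len(n)),
    style = styles,
    seed = seeds,
    duration = durations,
    utterance = pmap(
      list(styles, durations, seeds),
      function(s, d, sd) synth_utterance(s, d, sd, profiles = profiles)
    )
  )
}

#' Write / read a PCM WAV file
#'
#' Minimal mono 16-bit PCM WAV I/O for exporting and re-loading synthetic
#' utterances.
#'
#' @param x An `utterance`, or a numeric waveform in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sample rate; taken from the utterance when `x` is one.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a list
#'   with `waveform` and `sample_rate`.
#' @export
write_wav <- function(x, path, sample_rate = 16000) {
  if (inherits(x, "utterance")) {
    sample_rate <- x$sample_rate
    x <- x$waveform
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAV file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  readChar(con, 4) # WAVE
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    len <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), len %/% 2, size = 2,
                     signed = FALSE, endian = "little")
      sr <- fmt[3] + 65536 * fmt[4]
    } else if (id == "data") {
      pcm <- readBin(con, integer(), len %/% 2, size = 2, endian = "little")
      return(list(waveform = pcm / 32767, sample_rate = sr))
    } else {
      invisible(readBin(con, raw(), len))
    }
  }
}
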