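# Acoustic feature extraction: frame-level MFCCs (segmental stream) and
# utterance-level prosodic statistics (supra-segmental stream).

as_waveform <- function(x) {
  if (inherits(x, "utterance")) {
    list(wave = x$waveform, sr = x$sample_rate)
  } else if (is.list(x) && !is.null(x$waveform)) {
    list(wave = x$waveform, sr = x$sample_rate %||% 16000)
  } else if (is.numeric(x)) {
    list(wave = as.numeric(x), sr = 16000)
  } else {
    abort("expected an utterance, a list with $waveform, or a numeric vector")
  }
}

# Resample to the working rate before framing; all frame geometry below is
# defined at 16 kHz.
to_16k <- function(wave, sr, target = 16000) {
  if (sr == target) return(wave)
  if (sr < 8000) abort("sample rate must be >= 8 kHz")
  g <- gcd_int(target, sr)
  as.numeric(signal::resample(wave, target / g, sr / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

frame_signal <- function(wave, frame_len, hop) {
  n <- length(wave)
  if (n < frame_len) abort("signal shorter than one frame")
  n_frames <- floor((n - frame_len) / hop) + 1L
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  matrix(wave[idx], nrow = frame_len)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, n_fft, sr, f_lo = 0, f_hi = sr / 2) {
  mel_pts <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_mels + 2)
  bin <- floor((n_fft + 1) * mel_to_hz(mel_pts) / sr)
  n_bins <- n_fft %/% 2 + 1
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- bin[m]; ce <- bin[m + 1]; hi <- bin[m + 2]
    if (ce > lo)  fb[m, (lo + 1):(ce + 1)] <- (lo:ce - lo) / (ce - lo)
    if (hi > ce)  fb[m, (ce + 1):(hi + 1)] <- (hi - ce:hi) / (hi - ce)
  }
  fb
}

#' Extract frame-level MFCC features (segmental stream)
#'
#' Mel-frequency cepstral coefficients per 25 ms Hamming frame at a 10 ms hop
#' (defaults), computed at 16 kHz after internal resampling: pre-emphasis
#' 0.97, 512-point FFT, 26 triangular Mel filters, orthonormal DCT-II keeping
#' coefficients 1..13 (c0 excluded), with the log frame energy appended as a
#' final column. Deterministic.
#'
#' @param x An `utterance`, a list with `$waveform`/`$sample_rate`, or a
#'   numeric waveform (assumed 16 kHz).
#' @param n_mfcc Number of cepstral coefficients kept (excluding c0).
#' @param n_mels Number of Mel filters.
#' @param frame_ms,hop_ms Frame length and hop in milliseconds.
#' @param preemphasis Pre-emphasis coefficient.
#' @param append_energy Append log frame energy as an extra column.
#' @return List of class `segmental_features`: `features` (frames x
#'   coefficients matrix) and `frame_times` (frame start times, seconds).
#' @examples
#' u <- synth_utterance("parentese", 1, seed = 1)
#' dim(extract_segmental(u)$features)
#' @export
extract_segmental <- function(x, n_mfcc = 13, n_mels = 26, frame_ms = 25,
                              hop_ms = 10, preemphasis = 0.97,
                              append_energy = TRUE) {
  w <- as_waveform(x)
  wave <- to_16k(w$wave, w$sr)
  sr <- 16000
  frame_len <- round(frame_ms / 1000 * sr)
  hop <- round(hop_ms / 1000 * sr)

  pre <- c(wave[1], wave[-1] - preemphasis * wave[-length(wave)])
  frames <- frame_signal(pre, frame_len, hop)
  frames_raw <- frame_signal(wave, frame_len, hop)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  frames <- frames * win

  n_fft <- 2^ceiling(log2(frame_len))
  padded <- rbind(frames, matrix(0, n_fft - frame_len, ncol(frames)))
  spec <- stats::mvfft(padded)
  pow <- (Mod(spec[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2) / n_fft

  fb <- mel_filterbank(n_mels, n_fft, sr)
  fbe <- log(pmax(fb %*% pow, 1e-10))

  m <- seq_len(n_mels)
  dct <- sqrt(2 / n_mels) *
    outer(seq_len(n_mfcc), m, function(i, j) cos(pi * i * (j - 0.5) / n_mels))
  cep <- t(dct %*% fbe)

  if (append_energy) {
    loge <- log(pmax(colSums(frames_raw^2), 1e-10))
    cep <- cbind(cep, loge)
  }
  colnames(cep) <- c(paste0("mfcc", seq_len(n_mfcc)),
                     if (append_energy) "log_energy")
  structure(
    list(features = cep,
         frame_times = (seq_len(ncol(frames)) - 1L) * hop / sr),
    class = "segmental_features"
  )
}

#' Estimate the fundamental-frequency contour
#'
#' Short-time autocorrelation F0 tracking: 40 ms frames at a 10 ms hop,
#' normalised autocorrelation maximised over the lag band corresponding to the
#' F0 search range (default 75-600 Hz) with parabolic peak interpolation. A
#' frame is voiced when its autocorrelation peak exceeds the periodicity
#' threshold and its energy is not negligible relative to the utterance peak.
#'
#' @inheritParams extract_segmental
#' @param f0_min,f0_max F0 search band, Hz; must satisfy `f0_min < f0_max`.
#' @param frame_ms,hop_ms Analysis frame and hop, milliseconds.
#' @param periodicity_threshold Minimum normalised autocorrelation peak for a
#'   voiced decision.
#' @param energy_threshold Voiced frames must exceed this fraction of the
#'   maximum frame RMS.
#' @return A tibble with `time`, `f0` (Hz, `NA` where unvoiced) and `voiced`.
#' @examples
#' u <- synth_utterance("adult_directed", 1, seed = 2)
#' f0 <- estimate_f0_contour(u)
#' mean(f0$f0[f0$voiced])
#' @export
estimate_f0_contour <- function(x, f0_min = 75, f0_max = 600, frame_ms = 40,
                                hop_ms = 10, periodicity_threshold = 0.5,
                                energy_threshold = 0.05) {
  if (f0_min >= f0_max || f0_min <= 0) abort("need 0 < f0_min < f0_max")
  w <- as_waveform(x)
  wave <- to_16k(w$wave, w$sr)
  sr <- 16000
  frame_len <- round(frame_ms / 1000 * sr)
  hop <- round(hop_ms / 1000 * sr)
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- ceiling(sr / f0_min)
  if (lag_max >= frame_len) abort("frame too short for `f0_min`")

  frames <- frame_signal(wave, frame_len, hop)
  frames <- sweep(frames, 2, colMeans(frames))
  rms <- sqrt(colMeans(frames^2))

  n_fft <- 2^ceiling(log2(2L * frame_len))
  padded <- rbind(frames, matrix(0, n_fft - frame_len, ncol(frames)))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(Mod(spec)^2, inverse = TRUE)) / n_fft
  r0 <- pmax(ac[1, ], 1e-12)

  n_frames <- ncol(frames)
  f0 <- rep(NA_real_, n_frames)
  peak <- numeric(n_frames)
  lags <- lag_min:lag_max
  for (j in seq_len(n_frames)) {
    r <- ac[lags + 1L, j] / r0[j]
    k <- which.max(r)
    peak[j] <- r[k]
    lag <- lags[k]
    # parabolic interpolation around the peak (in lag domain)
    if (k > 1 && k < length(lags)) {
      ym <- r[k - 1]; y0 <- r[k]; yp <- r[k + 1]
      denom <- ym - 2 * y0 + yp
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (ym - yp) / denom
    }
    f0[j] <- sr / lag
  }
  voiced <- peak >= periodicity_threshold & rms >= energy_threshold * max(rms)
  f0[!voiced] <- NA_real_
  tibble(time = (seq_len(n_frames) - 1L) * hop / sr, f0 = f0, voiced = voiced)
}

#' Extract utterance-level prosodic statistics (supra-segmental stream)
#'
#' Fixed-length prosodic feature vector per utterance: F0 mean, SD, minimum,
#' maximum, range and least-squares slope over voiced frames; frame-energy
#' mean, SD and range in dB over all frames; total duration; and the voiced
#' fraction. F0 statistics of an utterance with no voiced frame are returned
#' as `NA` (with a warning): such an utterance is classifiable only through
#' its segmental stream.
#'
#' @inheritParams estimate_f0_contour
#' @param ... Passed to [estimate_f0_contour()].
#' @return One-row tibble of class `suprasegmental_features` with columns
#'   `f0_mean`, `f0_sd`, `f0_min`, `f0_max`, `f0_range`, `f0_slope` (Hz/s),
#'   `energy_mean`, `energy_sd`, `energy_range` (dB), `duration` (s),
#'   `voiced_fraction`.
#' @export
extract_suprasegmental <- function(x, ...) {
  w <- as_waveform(x)
  wave <- to_16k(w$wave, w$sr)
  sr <- 16000
  duration <- length(wave) / sr
  contour <- estimate_f0_contour(list(waveform = wave, sample_rate = sr), ...)

  frame_len <- round(0.025 * sr); hop <- round(0.010 * sr)
  frames <- frame_signal(wave, frame_len, hop)
  en_db <- 10 * log10(colMeans(frames^2) + 1e-12)

  v <- contour$f0[contour$voiced]
  if (length(v) == 0) {
    warn("utterance has no voiced frames; F0 statistics set to NA")
    f0_stats <- rep(NA_real_, 6)
  } else {
    slope <- if (length(v) >= 2) {
      tv <- contour$time[contour$voiced]
      unname(stats::coef(stats::lm(v ~ tv))[2])
    } else 0
    f0_stats <- c(mean(v), if (length(v) >= 2) stats::sd(v) else 0,
                  min(v), max(v), max(v) - min(v), slope)
  }
  out <- tibble(
    f0_mean = f0_stats[1], f0_sd = f0_stats[2], f0_min = f0_stats[3],
    f0_max = f0_stats[4], f0_range = f0_stats[5], f0_slope = f0_stats[6],
    energy_mean = mean(en_db), energy_sd = stats::sd(en_db),
    energy_range = max(en_db) - min(en_db),
    duration = duration, voiced_fraction = mean(contour$voiced)
  )
  class(out) <- c("suprasegmental_features", class(out))
  out
}
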