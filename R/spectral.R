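#' Spectral pitch estimate from a sampled waveform
#'
#' A minimal fundamental-frequency estimator for flat, harmonically clean
#' syllable segments: a Hann-windowed magnitude spectrum is computed over the
#' analysis window, the lowest harmonic is located as the first local maximum
#' above a relative-power threshold, and the returned pitch is the
#' power-weighted mean frequency within a few bins of that peak. Intended for
#' synthetic waveforms; syllable segmentation and real song audio are out of
#' scope.
#'
#' @param waveform Numeric vector of mono PCM samples.
#' @param sample_rate Sampling rate in Hz.
#' @param window Optional `c(start, end)` time interval in seconds; defaults
#'   to the whole waveform.
#' @param min_freq Lowest candidate frequency in Hz (rejects DC and rumble).
#' @param rel_threshold Relative power threshold (fraction of the global
#'   spectral peak) a local maximum must exceed to count as the lowest
#'   harmonic.
#' @param n_side_bins Number of FFT bins on each side of the peak included in
#'   the power-weighted mean.
#' @return Estimated pitch in Hz.
#' @export
extract_pitch <- function(waveform, sample_rate, window = NULL,
                          min_freq = 250, rel_threshold = 0.1,
                          n_side_bins = 3L) {
  stopifnot(is.numeric(waveform), sample_rate > 0)
  if (!is.null(window)) {
    i0 <- max(1L, floor(window[1] * sample_rate) + 1L)
    i1 <- min(length(waveform), ceiling(window[2] * sample_rate))
    if (i1 <= i0) stop("analysis window lies outside the waveform")
    waveform <- waveform[i0:i1]
  }
  n <- length(waveform)
  if (n < 8L) stop("window too short for spectral analysis")
  if (all(waveform == 0)) stop("silent window: cannot extract pitch")
  hann <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L))
  spec <- fft(waveform * hann)
  nb <- floor(n / 2) + 1L
  power <- Mod(spec[seq_len(nb)])^2
  freq <- (seq_len(nb) - 1L) * sample_rate / n
  lo <- which(freq >= min_freq)[1L]
  if (is.na(lo) || lo >= nb - 1L)
    stop("window too short for the configured spectral resolution")
  thr <- rel_threshold * max(power[lo:nb])
  peak <- NA_integer_
  for (i in seq.int(max(lo, 2L), nb - 1L)) {
    if (power[i] >= thr && power[i] > power[i - 1L] && power[i] >= power[i + 1L]) {
      peak <- i
      break
    }
  }
  if (is.na(peak)) stop("no spectral peak above threshold; cannot extract pitch")
  idx <- seq.int(max(lo, peak - n_side_bins), min(nb, peak + n_side_bins))
  sum(freq[idx] * power[idx]) / sum(power[idx])
}

#' Synthesize a harmonic stack test tone
#'
#' Helper for exercising [extract_pitch()]: a sum of sinusoids at integer
#' multiples of `f0` with the given relative amplitudes, optionally with
#' additive white Gaussian noise at a stated level relative to the fundamental.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @param harmonics Amplitudes of successive harmonics (first = fundamental).
#' @param noise_db Noise level in dB relative to the fundamental amplitude;
#'   `-Inf` (default) for none. Uses the current RNG stream.
#' @return Numeric vector of samples.
#' @export
harmonic_stack <- function(f0, sample_rate = 44100, duration = 0.032,
                           harmonics = c(1, 0.5, 0.25), noise_db = -Inf) {
  t <- seq.int(0L, round(duration * sample_rate) - 1L) / sample_rate
  y <- rowSums(vapply(seq_along(harmonics),
                      function(k) harmonics[k] * sin(2 * pi * k * f0 * t),
                      numeric(length(t))))
  if (is.finite(noise_db))
    y <- y + rnorm(length(y), sd = harmonics[1] * 10^(noise_db / 20))
  y
}
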