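# Shared DSP primitives for the synthetic soundscape generator: FFT-shaped
# Gaussian noise, brick-wall band-pass filtering, and analytic-signal
# envelopes. All operate on plain numeric vectors of pressure samples.

# frequency (Hz) of each FFT bin, folded to [0, fs/2]
.fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

# smallest 2-3-5-smooth length >= n (R's mixed-radix FFT degrades badly on
# lengths with large prime factors)
.fft_len <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  if (is.na(m)) stats::nextn(n, 2) else m
}

# Gaussian noise whose one-sided PSD follows density_db_fn(f) [dB re 1 uPa^2/Hz].
# density_db_fn may return -Inf for bins to silence. Generated at a smooth
# FFT length and truncated; truncation does not alter the statistics.
.shaped_noise <- function(n, fs, density_db_fn) {
  m <- .fft_len(n)
  x <- stats::rnorm(m)
  f <- .fft_freqs(m, fs)
  d <- density_db_fn(f)
  h <- sqrt(db_to_linear(d) * fs / 2)
  h[!is.finite(d)] <- 0
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / m
  y[seq_len(n)]
}

# zero all spectral content outside [low, high] Hz; zero-padded to a smooth
# FFT length (the pad is discarded)
.fft_bandpass <- function(x, fs, low, high) {
  n <- length(x)
  m <- .fft_len(n)
  f <- .fft_freqs(m, fs)
  keep <- f >= low & f <= high
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) * keep, inverse = TRUE)) / m
  y[seq_len(n)]
}

# magnitude of the analytic signal (Hilbert envelope), zero-padded as above
.envelope <- function(x) {
  n <- length(x)
  m <- .fft_len(n)
  h <- numeric(m)
  h[1] <- 1
  if (m %% 2 == 0) {
    h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[2:((m + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(stats::fft(c(x, numeric(m - n))) * h, inverse = TRUE) / m)
  env[seq_len(n)]
}

.rms <- function(x) sqrt(mean(x^2))

#' Ambient noise bed specification
#'
#' The synthetic ambient sound floor: Gaussian noise with a gently sloping
#' spectral density `level_db_at_ref + slope_db_per_decade * log10(f/ref_hz)`
#' dB re 1 uPa^2/Hz. Below `floor_hz` the density is held at its `floor_hz`
#' value (the analysis discards those frequencies anyway).
#'
#' @param level_db_at_ref density at the reference frequency, dB re 1 uPa^2/Hz.
#' @param slope_db_per_decade spectral slope (negative = red spectrum).
#' @param ref_hz reference frequency, Hz.
#' @param floor_hz frequency below which the density is held constant.
#' @return object of class `ambient_spec`.
#' @export
ambient_spec <- function(level_db_at_ref = 60, slope_db_per_decade = -5,
                         ref_hz = 1000, floor_hz = 10) {
  .check(is.finite(level_db_at_ref) && is.finite(slope_db_per_decade),
         "ambient levels must be finite")
  structure(list(level_db_at_ref = level_db_at_ref,
                 slope_db_per_decade = slope_db_per_decade,
                 ref_hz = ref_hz, floor_hz = floor_hz),
            class = "ambient_spec")
}

# density function (dB re 1 uPa^2/Hz) of an ambient bed
.ambient_density_fn <- function(spec) {
  function(f) {
    fe <- pmax(f, spec$floor_hz)
    spec$level_db_at_ref + spec$slope_db_per_decade * log10(fe / spec$ref_hz)
  }
}

#' Synthesise an ambient noise segment
#'
#' @param spec an [ambient_spec()].
#' @param duration_s segment length, s.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so a caller can drive several stages from one seeded stream).
#' @return numeric pressure vector, uPa.
#' @export
synth_ambient_noise <- function(spec, duration_s, fs, seed = NULL) {
  .check(inherits(spec, "ambient_spec"), "spec must be an ambient_spec")
  if (!is.null(seed)) set.seed(seed)
  .shaped_noise(round(duration_s * fs), fs, .ambient_density_fn(spec))
}

#' Vessel noise specification
#'
#' Stylised broadband vessel noise: spectral density
#' `level_db_at_ref + slope_db_per_decade * log10(f/ref_hz)` dB re 1 uPa^2/Hz
#' up to `rolloff_hz`, and no injected energy above `rolloff_hz`. The rolloff
#' is the ground-truth masking frequency of a synthetic event: above it the
#' vessel contributes nothing, so its excess over the ambient bed is <= 0 by
#' construction.
#'
#' @param level_db_at_ref density at `ref_hz`, dB re 1 uPa^2/Hz.
#' @param slope_db_per_decade spectral slope.
#' @param rolloff_hz ground-truth masking frequency, Hz (must exceed 100 Hz).
#' @param duration_s nominal duration of the vessel passage, s.
#' @param ref_hz reference frequency, Hz.
#' @param floor_hz frequency below which the density is held constant.
#' @return object of class `vessel_noise_spec`.
#' @export
vessel_noise_spec <- function(level_db_at_ref = 95, slope_db_per_decade = -10,
                              rolloff_hz = 50000, duration_s = 300,
                              ref_hz = 1000, floor_hz = 10) {
  .check(is.finite(level_db_at_ref) && is.finite(slope_db_per_decade),
         "vessel levels must be finite")
  .check(rolloff_hz > 100, "rolloff_hz must exceed 100 Hz")
  .check(duration_s > 0, "duration_s must be positive")
  structure(list(level_db_at_ref = level_db_at_ref,
                 slope_db_per_decade = slope_db_per_decade,
                 rolloff_hz = rolloff_hz, duration_s = duration_s,
                 ref_hz = ref_hz, floor_hz = floor_hz),
            class = "vessel_noise_spec")
}

#' Synthesise a vessel-noise segment
#'
#' @param spec a [vessel_noise_spec()]. The rolloff may be at or above
#'   Nyquist, in which case the vessel spans the full analysed bandwidth
#'   (a full-band masking event).
#' @param fs sampling rate, Hz.
#' @param duration_s segment length, s (defaults to `spec$duration_s`).
#' @param seed optional integer seed (see [synth_ambient_noise()]).
#' @return numeric pressure vector, uPa.
#' @export
synth_vessel_noise <- function(spec, fs, duration_s = spec$duration_s,
                               seed = NULL) {
  .check(inherits(spec, "vessel_noise_spec"), "spec must be a vessel_noise_spec")
  if (!is.null(seed)) set.seed(seed)
  dens <- function(f) {
    fe <- pmax(f, spec$floor_hz)
    d <- spec$level_db_at_ref +
      spec$slope_db_per_decade * log10(fe / spec$ref_hz)
    d[f > spec$rolloff_hz] <- -Inf
    d
  }
  .shaped_noise(round(duration_s * fs), fs, dens)
}
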