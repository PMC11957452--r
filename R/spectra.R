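#' Welch sound spectral density levels (SSDL)
#'
#' Estimates the power spectral density of a calibrated pressure clip by the
#' Welch method: 1-s Hann windows with 50% overlap, snapshots averaged in
#' linear power, reported as sound spectral density levels in
#' dB re 1 uPa^2/Hz on a 1-Hz frequency grid. The window is normalised by its
#' mean-square value so band-limited white noise of variance sigma^2 yields a
#' density of sigma^2/(fs/2). Bins below `f_min` (default 100 Hz, where
#' shallow-water propagation and flow noise make levels uninterpretable) are
#' discarded.
#'
#' @param clip a `calibrated_clip` (see [wav_to_pressure()]).
#' @param window_s analysis window length in seconds (default 1, giving
#'   1-Hz bins).
#' @param overlap fractional window overlap (default 0.5).
#' @param f_min lowest analysis frequency retained, Hz.
#' @return object of class `spectrum_ssdl`: list with `freq_hz`, `level_db`,
#'   `df_hz` (bin width), `n_avg` (snapshots averaged), `fs`.
#' @export
welch_ssdl <- function(clip, window_s = 1, overlap = 0.5, f_min = 100) {
  .check(inherits(clip, "calibrated_clip"), "clip must be a calibrated_clip")
  fs <- clip$fs
  x <- clip$pressure
  nfft <- round(window_s * fs)
  .check(length(x) >= nfft,
         "clip (%d samples) shorter than one %g-s analysis window", length(x), window_s)
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)      # Hann (periodic)
  norm <- fs * sum(w^2)                                    # density scaling
  n_half <- nfft %/% 2
  acc <- numeric(n_half + 1)
  segs <- matrix(0, nfft, length(starts))
  for (i in seq_along(starts)) {
    segs[, i] <- x[starts[i]:(starts[i] + nfft - 1L)] * w
  }
  ft <- stats::mvfft(segs)
  p <- Mod(ft[seq_len(n_half + 1), , drop = FALSE])^2 / norm
  # one-sided: double interior bins (DC and Nyquist are not)
  if (n_half > 1) p[2:n_half, ] <- 2 * p[2:n_half, ]
  acc <- rowMeans(p)
  freq <- (0:n_half) * fs / nfft
  keep <- freq >= f_min
  structure(list(freq_hz = freq[keep], level_db = linear_to_db(acc[keep]),
                 df_hz = fs / nfft, n_avg = length(starts), fs = fs),
            class = "spectrum_ssdl")
}

#' @export
print.spectrum_ssdl <- function(x, ...) {
  cat(sprintf("<spectrum_ssdl> %d bins, %.4g-%.4g Hz (df=%g Hz), %d snapshots\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz), x$df_hz, x$n_avg))
  invisible(x)
}

#' Average spectra in linear power
#'
#' Per-bin mean of several SSDL spectra, computed on the linear power scale
#' (uPa^2/Hz) and returned in dB. All spectra must share the same frequency
#' grid.
#'
#' @param spectra list of `spectrum_ssdl` objects.
#' @return a `spectrum_ssdl` with `n_avg` summed over inputs.
#' @export
mean_ssdl <- function(spectra) {
  .check(length(spectra) >= 1, "need at least one spectrum")
  f0 <- spectra[[1]]$freq_hz
  for (s in spectra) {
    .check(length(s$freq_hz) == length(f0) && all(s$freq_hz == f0),
           "spectra are on different frequency grids")
  }
  lin <- rowMeans(vapply(spectra, function(s) db_to_linear(s$level_db),
                         numeric(length(f0))))
  out <- spectra[[1]]
  out$level_db <- linear_to_db(lin)
  out$n_avg <- sum(vapply(spectra, function(s) s$n_avg, numeric(1)))
  out
}

#' Base-10 one-third-octave band table
#'
#' Band centres at `10^(n/10)` Hz with edge ratio `10^(1/20)` on either side
#' (IEC base-10 convention). Returns the full bands whose lower edge is at or
#' above `f_min` and whose upper edge is at or below `f_max`.
#'
#' @param f_min,f_max frequency range to cover, Hz.
#' @return data.frame with `band_index`, `center_hz`, `lower_hz`, `upper_hz`.
#' @export
third_octave_bands <- function(f_min = 100, f_max = 144000) {
  .check(f_min > 0 && f_max > f_min, "need 0 < f_min < f_max")
  n <- seq(ceiling(10 * log10(f_min * 10^(1 / 20))),
           floor(10 * log10(f_max / 10^(1 / 20))))
  centers <- 10^(n / 10)
  data.frame(band_index = n, center_hz = centers,
             lower_hz = centers / 10^(1 / 20), upper_hz = centers * 10^(1 / 20))
}

#' Integrate an SSDL spectrum into one-third-octave band levels
#'
#' Band level = 10 log10 of the in-band sum of linear spectral density times
#' the bin width, in dB re 1 uPa. Only bands fully covered by the spectrum's
#' grid are returned; bins are assigned to bands by half-open intervals
#' `[lower, upper)`.
#'
#' @param spec a `spectrum_ssdl`.
#' @param bands optional band table from [third_octave_bands()]; defaults to
#'   all full bands within the spectrum's coverage.
#' @return object of class `third_octave_spectrum`: data.frame with band
#'   geometry, `level_db`, and `n_bins` per band.
#' @export
third_octave_levels <- function(spec, bands = NULL) {
  .check(inherits(spec, "spectrum_ssdl"), "spec must be a spectrum_ssdl")
  if (is.null(bands)) {
    bands <- third_octave_bands(min(spec$freq_hz), max(spec$freq_hz) + spec$df_hz)
  }
  .check(nrow(bands) >= 1, "spectrum does not cover a full one-third-octave band")
  lin <- db_to_linear(spec$level_db)
  level <- numeric(nrow(bands))
  nb <- integer(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    sel <- spec$freq_hz >= bands$lower_hz[i] & spec$freq_hz < bands$upper_hz[i]
    nb[i] <- sum(sel)
    level[i] <- if (nb[i] > 0) linear_to_db(sum(lin[sel]) * spec$df_hz) else NA_real_
  }
  out <- cbind(bands, level_db = level, n_bins = nb)
  class(out) <- c("third_octave_spectrum", "data.frame")
  out
}
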