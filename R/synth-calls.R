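#' Parametric call template
#'
#' Describes one synthetic beluga-like vocalisation. Pulsed classes (HFBP_M,
#' HFBP_B, CC, BUZZ) are trains of short band-passed transients; WHISTLE is a
#' frequency-modulated tone with harmonics. HFBP templates must start at or
#' above 20 kHz (the ultrasonic gate defining the class); HFBP_B templates
#' carry a biphonal low-frequency component separated from the main band by a
#' silent spectral gap; BUZZ templates must have a negative inter-pulse
#' interval trend (the repetition rate accelerates, as in terminal
#' echolocation buzzes).
#'
#' @param call_class one of `"HFBP_M"`, `"HFBP_B"`, `"CC"`, `"WHISTLE"`,
#'   `"BUZZ"`.
#' @param band_low_hz,band_high_hz main-band edges, Hz.
#' @param duration_s call duration, s.
#' @param level_db apparent RMS level of the call, dB re 1 uPa.
#' @param pulse_rate_hz initial pulse repetition rate (pulsed classes).
#' @param ipi_trend fractional change of the inter-pulse interval over the
#'   call (0 = constant rate; negative = accelerating).
#' @param ipi_jitter_cv multiplicative jitter on individual intervals.
#' @param pulse_len_s length of each transient, s (default 0.3 ms).
#' @param lf_component optional list `(f0_hz, bandwidth_hz, level_db)` for the
#'   biphonal low-frequency element (required for HFBP_B).
#' @return object of class `call_template`.
#' @export
call_template <- function(call_class, band_low_hz, band_high_hz, duration_s,
                          level_db, pulse_rate_hz = 350, ipi_trend = 0,
                          ipi_jitter_cv = 0.08, pulse_len_s = 3e-4,
                          lf_component = NULL) {
  classes <- c("HFBP_M", "HFBP_B", "CC", "WHISTLE", "BUZZ")
  .check(call_class %in% classes, "unknown call class: %s", call_class)
  .check(duration_s > 0, "duration_s must be positive")
  .check(band_low_hz > 0 && band_low_hz < band_high_hz,
         "need 0 < band_low_hz < band_high_hz")
  .check(is.finite(level_db), "level_db must be finite")
  if (call_class %in% c("HFBP_M", "HFBP_B")) {
    .check(band_low_hz >= 20000,
           "HFBP templates must have band_low_hz >= 20 kHz (got %.3g kHz)",
           band_low_hz / 1000)
  }
  if (call_class == "HFBP_B") {
    .check(!is.null(lf_component),
           "HFBP_B templates require an lf_component")
    .check(lf_component$f0_hz + lf_component$bandwidth_hz / 2 < band_low_hz,
           "lf_component must be separated from the main band by a silent gap")
  }
  if (call_class == "BUZZ") {
    .check(ipi_trend < 0, "BUZZ templates must have ipi_trend < 0")
  }
  structure(list(call_class = call_class, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, duration_s = duration_s,
                 level_db = level_db, pulse_rate_hz = pulse_rate_hz,
                 ipi_trend = ipi_trend, ipi_jitter_cv = ipi_jitter_cv,
                 pulse_len_s = pulse_len_s, lf_component = lf_component),
            class = "call_template")
}

# pulse onset times (s) for a pulsed template; IPI drifts linearly by
# ipi_trend over the call with multiplicative Gaussian jitter
.pulse_times <- function(template) {
  dur <- template$duration_s
  ipi0 <- 1 / template$pulse_rate_hz
  t <- 0
  times <- numeric(0)
  while (t <= dur - template$pulse_len_s) {
    times <- c(times, t)
    frac <- t / dur
    ipi <- ipi0 * (1 + template$ipi_trend * frac)
    ipi <- ipi * max(0.1, 1 + template$ipi_jitter_cv * stats::rnorm(1))
    t <- t + max(ipi, 2.5e-4)  # keep pulses resolvable
  }
  times
}

#' Synthesise one call from a template
#'
#' Pulsed classes are built as trains of Hann-windowed white-noise transients
#' whose inter-pulse interval follows the template's trend, then band-limited
#' to `[band_low_hz, band_high_hz]` with a sharp spectral edge so the
#' template band is the call's true spectral support. WHISTLE is a sinusoidal
#' FM fundamental with two harmonics confined to the template band. HFBP_B
#' adds the biphonal low-frequency component, band-limited to its own band,
#' leaving the spectral gap silent. The finished call is scaled so its RMS
#' level equals `level_db` exactly.
#'
#' @param template a [call_template()].
#' @param fs sampling rate, Hz (band must fit under Nyquist).
#' @param seed optional integer seed.
#' @return numeric pressure vector, uPa.
#' @export
synth_call <- function(template, fs, seed = NULL) {
  .check(inherits(template, "call_template"), "template must be a call_template")
  .check(template$band_high_hz <= fs / 2,
         "template band (%.3g kHz) exceeds Nyquist (%.3g kHz)",
         template$band_high_hz / 1000, fs / 2000)
  if (!is.null(seed)) set.seed(seed)
  n <- round(template$duration_s * fs)
  .check(n >= 8, "duration too short at this sampling rate")
  x <- numeric(n)
  if (template$call_class == "WHISTLE") {
    t <- (seq_len(n) - 1) / fs
    f_lo <- template$band_low_hz
    f_hi <- template$band_high_hz / 3          # fundamental; harmonics fill band
    inst <- f_lo + (f_hi - f_lo) * (0.5 - 0.5 * cos(2 * pi * t / template$duration_s))
    phase <- 2 * pi * cumsum(inst) / fs
    x <- sin(phase) + 0.5 * sin(2 * phase) + 0.25 * sin(3 * phase)
  } else {
    np <- max(4L, round(template$pulse_len_s * fs))
    win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(np) - 1) / (np - 1))
    times <- .pulse_times(template)
    .check(length(times) >= 4,
           "duration %.3g s holds fewer than 3 inter-pulse intervals",
           template$duration_s)
    for (tt in times) {
      i0 <- round(tt * fs) + 1L
      i1 <- min(i0 + np - 1L, n)
      idx <- i0:i1
      x[idx] <- x[idx] + win[seq_along(idx)] * stats::rnorm(length(idx))
    }
  }
  x <- .fft_bandpass(x, fs, template$band_low_hz, template$band_high_hz)
  x <- x * 10^(template$level_db / 20) / .rms(x)
  lf <- template$lf_component
  if (!is.null(lf)) {
    t <- (seq_len(n) - 1) / fs
    f_lo <- max(lf$f0_hz - lf$bandwidth_hz / 2, 50)
    f_hi <- lf$f0_hz + lf$bandwidth_hz / 2
    inst <- lf$f0_hz * (1 + 0.15 * sin(2 * pi * t / template$duration_s))
    phase <- 2 * pi * cumsum(inst) / fs
    y <- sin(phase) + 0.5 * sin(2 * phase)
    y <- .fft_bandpass(y, fs, f_lo, min(f_hi * 2.5, template$band_low_hz * 0.5))
    lf_level <- if (is.null(lf$level_db)) template$level_db - 10 else lf$level_db
    x <- x + y * 10^(lf_level / 20) / .rms(y)
  }
  x
}

#' Draw a call template from a class's population distribution
#'
#' Parameter distributions emulate the measured acoustic parameters of
#' St Lawrence beluga calls: HFBP main-band onsets are normal
#' (HFBP-M 36.4 +/- 6.5 kHz truncated at 30 kHz, the class's definitional
#' floor; HFBP-B 34.5 +/- 6.7 kHz truncated at the 20 kHz ultrasonic gate)
#' with the band extending to Nyquist; durations are normal 0.4 +/- 0.3 s
#' truncated to at least 0.15 s; contact calls span 200 Hz to Nyquist and
#' last over a second; whistles are 2-20 kHz FM tones; buzzes accelerate
#' (ipi_trend -0.8). Draws use the current RNG stream.
#'
#' @param call_class template class (see [call_template()]).
#' @param fs sampling rate, Hz.
#' @return a [call_template()].
#' @export
sample_call_template <- function(call_class, fs = 288000) {
  nyq <- fs / 2
  rtnorm <- function(mean, sd, lo, hi) {
    min(max(stats::rnorm(1, mean, sd), lo), hi)
  }
  switch(call_class,
    HFBP_M = call_template("HFBP_M",
      band_low_hz = 1000 * rtnorm(36.4, 6.5, 30, 60),
      band_high_hz = nyq,
      duration_s = rtnorm(0.4, 0.3, 0.15, 1.5),
      level_db = 135),
    HFBP_B = call_template("HFBP_B",
      band_low_hz = 1000 * rtnorm(34.5, 6.7, 20, 60),
      band_high_hz = nyq,
      duration_s = rtnorm(0.4, 0.4, 0.15, 1.5),
      level_db = 135,
      lf_component = list(f0_hz = 1000 * rtnorm(1.5, 0.5, 0.5, 3),
                          bandwidth_hz = 1500, level_db = 126)),
    CC = call_template("CC",
      band_low_hz = 200, band_high_hz = nyq,
      duration_s = rtnorm(1.3, 0.3, 0.7, 2.5),
      level_db = 140, pulse_rate_hz = 250),
    WHISTLE = call_template("WHISTLE",
      band_low_hz = 1000 * rtnorm(3, 1, 2, 5),
      band_high_hz = 20000,
      duration_s = rtnorm(0.8, 0.3, 0.3, 1.5),
      level_db = 130),
    BUZZ = call_template("BUZZ",
      band_low_hz = 1000 * rtnorm(33, 3, 25, 45),
      band_high_hz = nyq,
      duration_s = rtnorm(0.6, 0.2, 0.3, 1.2),
      level_db = 130, pulse_rate_hz = 120, ipi_trend = -0.8),
    stop(sprintf("unknown call class: %s", call_class), call. = FALSE))
}
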