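#' Hydrophone calibration specification
#'
#' End-to-end calibration of a recorder chain: `sensitivity_db` is the
#' end-to-end sensitivity in dB re 1 V/uPa (a large negative number), `gain_db`
#' any additional gain, and `peak_volts` the ADC full-scale voltage. Digital
#' full scale maps to `peak_volts`, so a digital sample x in \[-1,1\]
#' corresponds to a pressure of
#' `x * peak_volts * 10^(-(sensitivity_db + gain_db)/20)` uPa.
#'
#' @param sensitivity_db end-to-end sensitivity, dB re 1 V/uPa.
#' @param fs sampling rate, Hz.
#' @param bit_depth ADC resolution, 16 or 24 bits.
#' @param peak_volts ADC full-scale voltage (default 1 V).
#' @param gain_db additional gain, dB (default 0).
#' @param label free-text provenance label.
#' @return object of class `calibration_spec`.
#' @examples
#' cal <- soundtrap_hf300()
#' clip <- wav_to_pressure(c(0, 0.5, -0.5), cal)
#' @export
calibration_spec <- function(sensitivity_db, fs, bit_depth,
                             peak_volts = 1, gain_db = 0, label = "custom") {
  .check(is.finite(sensitivity_db), "sensitivity_db must be finite")
  .check(is.finite(fs) && fs > 0, "fs must be positive")
  .check(bit_depth %in% c(16L, 24L), "bit_depth must be 16 or 24")
  .check(is.finite(peak_volts) && peak_volts > 0, "peak_volts must be positive")
  structure(
    list(sensitivity_db = sensitivity_db, fs = fs,
         bit_depth = as.integer(bit_depth), peak_volts = peak_volts,
         gain_db = gain_db, label = label),
    class = "calibration_spec")
}

#' @describeIn calibration_spec SoundTrap HF300 preset: 288 kHz, 16-bit,
#'   -172.7 dB re 1 V/uPa end-to-end sensitivity.
#' @export
soundtrap_hf300 <- function() {
  calibration_spec(-172.7, 288000, 16L, label = "SoundTrap HF300")
}

#' @describeIn calibration_spec icListen HF preset: 256 kHz, 24-bit,
#'   -170 dB re 1 V/uPa end-to-end sensitivity.
#' @export
iclisten_hf <- function() {
  calibration_spec(-170, 256000, 24L, label = "icListen HF")
}

# uPa per unit digital full scale
.cal_scale <- function(cal) {
  cal$peak_volts * 10^(-(cal$sensitivity_db + cal$gain_db) / 20)
}

#' Convert digital samples to calibrated pressure
#'
#' Linear, invertible mapping from normalised digital samples to acoustic
#' pressure in micropascals using the end-to-end sensitivity.
#'
#' @param samples numeric vector in \[-1, 1\] (or a list from [read_wav()]).
#' @param cal a [calibration_spec()].
#' @return object of class `calibrated_clip`: list with `pressure` (uPa),
#'   `fs` (Hz), and `cal`.
#' @export
wav_to_pressure <- function(samples, cal) {
  .check(inherits(cal, "calibration_spec"), "cal must be a calibration_spec")
  if (is.list(samples)) {
    .check(samples$fs == cal$fs, "WAV fs (%s) disagrees with calibration fs (%s)",
           samples$fs, cal$fs)
    samples <- samples$samples
  }
  .check(all(is.finite(samples)), "samples must be finite")
  .check(max(abs(samples)) <= 1 + 1e-12, "digital samples must lie in [-1, 1]")
  structure(list(pressure = samples * .cal_scale(cal), fs = cal$fs, cal = cal),
            class = "calibrated_clip")
}

#' Convert calibrated pressure back to digital samples
#'
#' Inverse of [wav_to_pressure()]. Pressures beyond digital full scale clip
#' on a subsequent [write_wav()].
#'
#' @param clip a `calibrated_clip`, or a numeric pressure vector (uPa).
#' @param cal calibration to use (defaults to the clip's own).
#' @return numeric vector of digital samples.
#' @export
pressure_to_wav <- function(clip, cal = NULL) {
  if (inherits(clip, "calibrated_clip")) {
    if (is.null(cal)) cal <- clip$cal
    clip <- clip$pressure
  }
  .check(inherits(cal, "calibration_spec"), "cal must be a calibration_spec")
  clip / .cal_scale(cal)
}

#' Construct a calibrated clip directly from pressure samples
#'
#' @param pressure numeric vector, uPa.
#' @param cal a [calibration_spec()] recording provenance (and fs).
#' @return `calibrated_clip`.
#' @export
calibrated_clip <- function(pressure, cal) {
  .check(all(is.finite(pressure)), "pressure must be finite")
  structure(list(pressure = pressure, fs = cal$fs, cal = cal),
            class = "calibrated_clip")
}

#' @export
print.calibrated_clip <- function(x, ...) {
  cat(sprintf("<calibrated_clip> %d samples @ %g Hz (%.1f s), %s\n",
              length(x$pressure), x$fs, length(x$pressure) / x$fs,
              x$cal$label))
  invisible(x)
}
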