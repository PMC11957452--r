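#' Per-band signal excess of vessel noise over ambient
#'
#' The signal excess is the amount by which the during-exposure band level
#' exceeds the ambient reference, where the reference is the linear-power mean
#' of the before and after band levels:
#' `delta_b = L_during,b - 10*log10((10^(L_before,b/10) + 10^(L_after,b/10))/2)`.
#' A band where the excess is at or below zero is one where the vessel is
#' indiscernible from ambient.
#'
#' @param during,before,after `third_octave_spectrum` objects on identical
#'   band grids (see [third_octave_levels()]).
#' @return object of class `signal_excess`: data.frame with the band geometry
#'   and `delta_db`.
#' @export
signal_excess <- function(during, before, after) {
  for (s in list(during, before, after)) {
    .check(inherits(s, "third_octave_spectrum"),
           "inputs must be third_octave_spectrum objects")
  }
  .check(nrow(during) == nrow(before) && nrow(during) == nrow(after) &&
           all(during$band_index == before$band_index) &&
           all(during$band_index == after$band_index),
         "band grids differ between treatments")
  ref <- linear_to_db((db_to_linear(before$level_db) +
                         db_to_linear(after$level_db)) / 2)
  out <- data.frame(band_index = during$band_index,
                    center_hz = during$center_hz,
                    lower_hz = during$lower_hz,
                    upper_hz = during$upper_hz,
                    delta_db = during$level_db - ref)
  class(out) <- c("signal_excess", "data.frame")
  out
}

#' Masking frequency of a vessel-noise event
#'
#' The masking frequency `f_down` is the centre frequency of the lowest
#' one-third-octave band at which the signal excess is at or below the
#' threshold *and remains so for all higher bands* (a suffix condition, so a
#' single dip in a non-monotone excess curve does not qualify). Above
#' `f_down` the vessel is no longer discernible from ambient. A second,
#' conservative estimate `f_down_lower_hz` repeats the scan with the
#' threshold raised by `uncertainty_db` (default 3 dB, the nominal
#' hydrophone measurement uncertainty), giving a lower bound. If no band
#' qualifies, the event is flagged full-band: the vessel dominates across the
#' whole analysed bandwidth.
#'
#' @param excess a `signal_excess`.
#' @param uncertainty_db threshold shift for the lower-bound estimate, dB.
#' @param tie_tol_db numerical tie tolerance on the threshold comparison, dB.
#'   Excess values within `tie_tol_db` above the threshold count as at the
#'   threshold; the default 0.05 dB is far below measurement uncertainty.
#' @param event_id optional identifier carried into the result.
#' @return object of class `masking_result`: list with `f_down_hz`,
#'   `f_down_lower_hz` (NA when full-band), logical flags `full_band` and
#'   `full_band_lower`, and `event_id`.
#' @export
masking_frequency <- function(excess, uncertainty_db = 3, tie_tol_db = 0.05,
                              event_id = NA) {
  .check(inherits(excess, "signal_excess"), "excess must be a signal_excess")
  .check(nrow(excess) >= 2, "need at least two bands")
  scan <- function(threshold) {
    ok <- excess$delta_db <= threshold + tie_tol_db
    # lowest band from which all higher bands satisfy the condition
    suffix <- rev(cumprod(rev(ok))) > 0
    if (any(suffix)) excess$center_hz[which(suffix)[1]] else NA_real_
  }
  f_down <- scan(0)
  f_low <- scan(uncertainty_db)
  structure(list(f_down_hz = f_down, f_down_lower_hz = f_low,
                 full_band = is.na(f_down), full_band_lower = is.na(f_low),
                 event_id = event_id),
            class = "masking_result")
}

#' @export
print.masking_result <- function(x, ...) {
  cat(sprintf("<masking_result> event %s: f_down = %s, lower bound = %s\n",
              x$event_id,
              if (x$full_band) "full-band" else sprintf("%.3g kHz", x$f_down_hz / 1000),
              if (x$full_band_lower) "full-band" else sprintf("%.3g kHz", x$f_down_lower_hz / 1000)))
  invisible(x)
}

#' Summarise masking frequencies across events
#'
#' Mean, 1-sigma standard deviation and the 5/25/50/75/95% percentile
#' envelope (linear interpolation) of the defined masking frequencies.
#' Full-band events carry no finite masking frequency: they are excluded from
#' the summary and reported by count.
#'
#' @param results list of `masking_result` objects.
#' @return list with `n`, `n_full_band`, `mean_hz`, `sd_hz`,
#'   `percentiles_hz` (named numeric), and the underlying `f_down_hz` values.
#' @export
summarize_masking <- function(results) {
  .check(length(results) >= 1, "need at least one masking result")
  fd <- vapply(results, function(r) r$f_down_hz, numeric(1))
  n_full <- sum(is.na(fd))
  fd <- fd[!is.na(fd)]
  .check(length(fd) >= 1, "all events are full-band; no masking frequency defined")
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  list(n = length(fd), n_full_band = n_full,
       mean_hz = mean(fd),
       sd_hz = if (length(fd) > 1) stats::sd(fd) else 0,
       percentiles_hz = stats::quantile(fd, probs, names = TRUE, type = 7),
       f_down_hz = fd)
}

#' Shallow-water waveguide cutoff frequency
#'
#' In shallow water the bottom-limited waveguide acts as a high-pass filter:
#' signals below the quarter-wavelength cutoff
#' `f0 = cw / (4 z sqrt(1 - (cw/cb)^2))` do not propagate, where `z` is the
#' water depth, `cw` the sound speed in water and `cb` in the bottom.
#'
#' @param z depth, m.
#' @param cw sound speed in water, m/s.
#' @param cb sound speed in the bottom, m/s (must exceed `cw`).
#' @return cutoff frequency, Hz.
#' @examples
#' cutoff_frequency(z = 20, cw = 1450, cb = 1450 / 0.95)  # ~58 Hz
#' @export
cutoff_frequency <- function(z, cw, cb) {
  .check(z > 0, "depth must be positive")
  .check(cw > 0 && cb > cw,
         "need 0 < cw < cb (no cutoff when the bottom is acoustically slower)")
  cw / (4 * z * sqrt(1 - (cw / cb)^2))
}
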