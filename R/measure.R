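#' Measure Raven-style acoustic parameters of a call selection
#'
#' Computes the power spectrum of the selected stretch of audio (Welch,
#' 1024-point Hann windows, 50% overlap) and derives the standard selection
#' measurements: peak frequency (argmax of the spectrum within the
#' selection's frequency bounds), centre/Q1/Q3 frequencies (cumulative energy
#' fractions 0.50/0.25/0.75 within the bounds), and automated low/high
#' frequencies — the first and last frequencies at which the spectral density
#' exceeds `floor_db` (default -20 dB) relative to the peak. Durations are
#' `end_s - begin_s`.
#'
#' @param clip a `calibrated_clip` holding the audio the selection indexes.
#' @param sel one selection: list or one-row data.frame with `begin_s`,
#'   `end_s`, and optionally `low_hz`/`high_hz` analysis bounds (default
#'   0 to Nyquist).
#' @param floor_db spectral floor relative to the peak used for the automated
#'   low/high frequency bounds, dB.
#' @param nfft Welch window length, samples.
#' @return object of class `call_measurements`: list with `low_freq_khz`,
#'   `high_freq_khz`, `delta_time_s`, `delta_freq_khz`, `peak_freq_khz`,
#'   `center_freq_khz`, `q1_freq_khz`, `q3_freq_khz`.
#' @export
measure_call <- function(clip, sel, floor_db = -20, nfft = 1024) {
  .check(inherits(clip, "calibrated_clip"), "clip must be a calibrated_clip")
  fs <- clip$fs
  begin <- sel$begin_s; end <- sel$end_s
  .check(is.finite(begin) && is.finite(end) && begin < end,
         "selection must have begin_s < end_s")
  i0 <- max(1L, floor(begin * fs) + 1L)
  i1 <- min(length(clip$pressure), ceiling(end * fs))
  .check(i1 > i0, "selection is empty")
  x <- clip$pressure[i0:i1]
  lo_bound <- if (!is.null(sel$low_hz) && is.finite(sel$low_hz)) sel$low_hz else 0
  hi_bound <- if (!is.null(sel$high_hz) && is.finite(sel$high_hz)) sel$high_hz else fs / 2
  .check(hi_bound <= fs / 2, "selection bounds exceed Nyquist")

  nfft <- min(nfft, length(x))
  hop <- max(1L, nfft %/% 2)
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  segs <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w, numeric(nfft))
  ft <- stats::mvfft(as.matrix(segs))
  n_half <- nfft %/% 2
  p <- rowMeans(Mod(ft[seq_len(n_half + 1), , drop = FALSE])^2)
  freq <- (0:n_half) * fs / nfft

  inb <- freq >= lo_bound & freq <= hi_bound
  .check(any(inb), "no spectral bins inside the selection bounds")
  p_in <- p[inb]; f_in <- freq[inb]
  peak_i <- which.max(p_in)
  # automated low/high: first/last bin above the floor relative to the peak
  above <- which(p_in >= p_in[peak_i] * db_to_linear(floor_db))
  lo_i <- above[1]; hi_i <- above[length(above)]
  # energy-quantile frequencies over the call's measured spectral support,
  # so low <= q1 <= center <= q3 <= high by construction
  supp <- lo_i:hi_i
  cs <- cumsum(p_in[supp]) / sum(p_in[supp])
  qf <- function(q) f_in[supp[which(cs >= q)[1]]]
  structure(list(
    low_freq_khz = f_in[lo_i] / 1000,
    high_freq_khz = f_in[hi_i] / 1000,
    delta_time_s = end - begin,
    delta_freq_khz = (f_in[hi_i] - f_in[lo_i]) / 1000,
    peak_freq_khz = f_in[peak_i] / 1000,
    center_freq_khz = qf(0.50) / 1000,
    q1_freq_khz = qf(0.25) / 1000,
    q3_freq_khz = qf(0.75) / 1000),
    class = "call_measurements")
}

#' Measure every selection in a table
#'
#' @param clip a `calibrated_clip`.
#' @param selections data.frame of selections (see [read_selection_table()]).
#' @param ... passed to [measure_call()].
#' @return data.frame, one measurement row per selection.
#' @export
measure_selections <- function(clip, selections, ...) {
  rows <- lapply(seq_len(nrow(selections)), function(i) {
    as.data.frame(unclass(measure_call(clip, selections[i, ], ...)))
  })
  out <- do.call(rbind, rows)
  cbind(selections, out)
}
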