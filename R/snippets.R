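#' Extract call-free noise snippets from an annotated clip
#'
#' Selects `n` non-overlapping windows of `len_s` seconds that do not overlap
#' any annotated call, scanning from the start of the clip (earliest-first).
#' Concatenating the default 10 windows of 0.5 s yields the 5-s noise sample
#' used for spectral analysis of each treatment. Intervals are half-open
#' `[begin, end)` in seconds from clip start.
#'
#' @param clip a `calibrated_clip`.
#' @param selections data.frame of call annotations with `begin_s` and
#'   `end_s` columns (e.g. from [read_selection_table()]); may have zero rows.
#' @param n number of windows (default 10).
#' @param len_s window length in seconds (default 0.5).
#' @param step_s search step between candidate window starts; defaults to
#'   `len_s` (non-overlapping tiling).
#' @return list with `windows` (data.frame `begin_s`, `end_s`), and
#'   `noise` — a `calibrated_clip` holding the concatenated windows.
#' @export
extract_noise_snippets <- function(clip, selections = NULL, n = 10, len_s = 0.5,
                                   step_s = len_s) {
  .check(inherits(clip, "calibrated_clip"), "clip must be a calibrated_clip")
  dur <- length(clip$pressure) / clip$fs
  if (is.null(selections)) {
    selections <- data.frame(begin_s = numeric(0), end_s = numeric(0))
  }
  starts <- seq(0, dur - len_s, by = step_s)
  free <- function(b) {
    e <- b + len_s
    !any(selections$begin_s < e & selections$end_s > b)
  }
  picked <- numeric(0)
  for (b in starts) {
    if (length(picked) == n) break
    if ((length(picked) == 0 || b >= picked[length(picked)] + len_s) && free(b)) {
      picked <- c(picked, b)
    }
  }
  .check(length(picked) == n,
         "only %d call-free %.2g-s windows available (%d required)",
         length(picked), len_s, n)
  idx <- unlist(lapply(picked, function(b) {
    i0 <- floor(b * clip$fs) + 1L
    i0:(i0 + round(len_s * clip$fs) - 1L)
  }))
  list(windows = data.frame(begin_s = picked, end_s = picked + len_s),
       noise = calibrated_clip(clip$pressure[idx], clip$cal))
}
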