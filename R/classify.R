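#' Classifier configuration
#'
#' Operational thresholds behind the rule-based call classifier. The class
#' definitions fix the 20-kHz ultrasonic gate and the 30-kHz
#' no-low-frequency-energy condition for monophonic burst pulses; the
#' remaining thresholds operationalise qualitative criteria ("consistent
#' repetition rate", "immediately preceded or followed") and are configurable.
#'
#' @param hfbp_low_hz ultrasonic gate: minimum main-band low frequency for
#'   HFBP, Hz.
#' @param hfbp_m_clean_hz HFBP-M must show no energy (above the measurement
#'   floor) below this frequency, Hz.
#' @param max_ipi_cv maximum IPI coefficient of variation for a "consistent"
#'   pulse train.
#' @param buzz_slope buzz exclusion: fractional IPI decline per call at or
#'   below which a train counts as an accelerating echolocation buzz.
#' @param click_context_s exclusion window: a neighbouring echolocation click
#'   train within this many seconds marks the selection as a buzz, s.
#' @param cc_max_low_hz maximum low frequency for a contact call, Hz.
#' @param cc_min_bandwidth_hz minimum contact-call bandwidth, Hz.
#' @param cc_min_duration_s minimum contact-call duration, s.
#' @param min_pulses,min_rate_hz,max_rate_hz what counts as a pulse train.
#' @param lf_min_excess_db biphonation evidence: a low-frequency component
#'   must exceed ambient by this margin, dB.
#' @param lf_gap_db minimum spectral dip between the low-frequency component
#'   and the main band, dB.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(hfbp_low_hz = 20000, hfbp_m_clean_hz = 30000,
                              max_ipi_cv = 0.35, buzz_slope = -0.3,
                              click_context_s = 1, cc_max_low_hz = 20000,
                              cc_min_bandwidth_hz = 20000,
                              cc_min_duration_s = 0.5, min_pulses = 5,
                              min_rate_hz = 50, max_rate_hz = 5000,
                              lf_min_excess_db = 6, lf_gap_db = 10) {
  cfg <- as.list(environment())
  .check(all(vapply(cfg[c("hfbp_low_hz", "hfbp_m_clean_hz", "max_ipi_cv",
                          "click_context_s", "cc_min_duration_s")],
                    function(v) is.finite(v) && v > 0, logical(1))),
         "classifier thresholds must be positive")
  structure(cfg, class = "classifier_config")
}

#' Classify a measured call
#'
#' Applies the rule set in order: (1) a train whose inter-pulse interval
#' shrinks rapidly (fractional decline at or below `buzz_slope`) or that sits
#' within `click_context_s` of an echolocation click train is an excluded
#' buzz; (2) a consistent pulse train with its low frequency at or above the
#' 20-kHz gate is HFBP — biphonal (HFBP_B) when an isolated low-frequency
#' component with a silent spectral gap is in evidence, else monophonic
#' (HFBP_M), which additionally requires no energy below 30 kHz above the
#' measurement floor; (3) a pulsed, broadband (>= 20 kHz bandwidth), long
#' (>= 0.5 s) signal starting below 20 kHz is a contact call; (4) anything
#' else (whistles, short bursts) is OTHER. Deterministic: equal inputs give
#' equal classes.
#'
#' @param m a `call_measurements` (see [measure_call()]).
#' @param train a `pulse_train` for the call's main band (see
#'   [detect_pulses()]).
#' @param context optional list with `click_train_gap_s`: time to the nearest
#'   neighbouring echolocation click train, s (`Inf` when none).
#' @param lf optional biphonation evidence: list with `present` (logical),
#'   as from [lf_component_evidence()].
#' @param config a [classifier_config()].
#' @return character class: `"HFBP_M"`, `"HFBP_B"`, `"CC"`, `"OTHER"` or
#'   `"BUZZ_EXCLUDED"`.
#' @export
classify_call <- function(m, train, context = NULL, lf = NULL,
                          config = classifier_config()) {
  .check(inherits(m, "call_measurements"), "m must be call_measurements")
  .check(inherits(train, "pulse_train"), "train must be a pulse_train")
  pulsed <- train$n_pulses >= config$min_pulses &&
    is.finite(train$rate_hz) &&
    train$rate_hz >= config$min_rate_hz && train$rate_hz <= config$max_rate_hz
  # rule 1: echolocation buzz exclusion
  if (pulsed) {
    if (is.finite(train$ipi_slope) && train$ipi_slope <= config$buzz_slope) {
      return("BUZZ_EXCLUDED")
    }
    gap <- if (!is.null(context$click_train_gap_s)) context$click_train_gap_s else Inf
    if (gap <= config$click_context_s) return("BUZZ_EXCLUDED")
  }
  low_hz <- m$low_freq_khz * 1000
  consistent <- pulsed && is.finite(train$ipi_cv) &&
    train$ipi_cv <= config$max_ipi_cv
  # rule 2: ultrasonic burst pulses
  if (consistent && low_hz >= config$hfbp_low_hz) {
    lf_present <- !is.null(lf) && isTRUE(lf$present)
    if (lf_present) return("HFBP_B")
    if (low_hz >= config$hfbp_m_clean_hz) return("HFBP_M")
    return("OTHER")
  }
  # rule 3: contact calls
  if (pulsed && low_hz < config$cc_max_low_hz &&
      m$delta_freq_khz * 1000 >= config$cc_min_bandwidth_hz &&
      m$delta_time_s >= config$cc_min_duration_s) {
    return("CC")
  }
  "OTHER"
}

#' Evidence for a biphonal low-frequency component
#'
#' Inspects the selection's spectrum below the ultrasonic gate for an
#' isolated component: a sub-20-kHz region whose density exceeds the local
#' noise floor by at least `lf_min_excess_db`, separated from the main band
#' by a dip of at least `lf_gap_db` below the component's peak ("no acoustic
#' energy between the low and high frequency components"). The noise floor
#' is a robust line in dB versus log-frequency fitted to the low band, so a
#' sloped ambient (or vessel) spectrum does not masquerade as a component.
#' When vessel noise swamps the band, no evidence is found and the caller
#' falls back to the monophonic class — mirroring how masked biphonal calls
#' are pooled.
#'
#' @param clip a `calibrated_clip`.
#' @param sel the selection (list with `begin_s`, `end_s`, optional
#'   `low_hz` giving the main band's onset).
#' @param ambient_db optional known ambient reference density below 20 kHz,
#'   dB re 1 uPa^2/Hz, used instead of the fitted floor.
#' @param config a [classifier_config()].
#' @param nfft spectrum length, samples.
#' @return list with `present`, `f0_hz` (peak of the component, NA when
#'   absent), `gap_db` (depth of the dip).
#' @export
lf_component_evidence <- function(clip, sel, ambient_db = NULL,
                                  config = classifier_config(), nfft = 4096) {
  fs <- clip$fs
  i0 <- max(1L, floor(sel$begin_s * fs) + 1L)
  i1 <- min(length(clip$pressure), ceiling(sel$end_s * fs))
  x <- clip$pressure[i0:i1]
  nfft <- min(nfft, length(x))
  hop <- max(1L, nfft %/% 2)
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  segs <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w, numeric(nfft))
  ft <- stats::mvfft(as.matrix(segs))
  n_half <- nfft %/% 2
  p <- rowMeans(Mod(ft[seq_len(n_half + 1), , drop = FALSE])^2) / (fs * sum(w^2))
  freq <- (0:n_half) * fs / nfft
  main_low <- if (!is.null(sel$low_hz) && is.finite(sel$low_hz)) sel$low_hz
              else config$hfbp_m_clean_hz
  lowband <- freq > 100 & freq < config$hfbp_low_hz
  if (sum(lowband) < 8) {
    return(list(present = FALSE, f0_hz = NA_real_, gap_db = NA_real_))
  }
  # smooth over ~5 bins: tames single-bin estimation noise while leaving a
  # tonal component (hundreds of Hz wide) intact
  p_sm <- stats::filter(p[lowband], rep(1 / 5, 5), sides = 2)
  p_sm[is.na(p_sm)] <- p[lowband][is.na(p_sm)]
  p_lo <- linear_to_db(as.numeric(p_sm)); f_lo <- freq[lowband]
  if (is.null(ambient_db)) {
    # robust noise floor: median-based line in dB vs log-f (L1-ish via two
    # iterations of least squares on points at or below the current floor)
    lx <- log10(f_lo)
    fit <- stats::lsfit(lx, p_lo)
    for (it in 1:2) {
      resid <- p_lo - (fit$coefficients[1] + fit$coefficients[2] * lx)
      keep <- resid <= stats::quantile(resid, 0.8)
      fit <- stats::lsfit(lx[keep], p_lo[keep])
    }
    floor_db <- fit$coefficients[1] + fit$coefficients[2] * lx
  } else {
    floor_db <- rep(ambient_db, length(f_lo))
  }
  excess <- p_lo - floor_db
  peak_i <- which.max(excess)
  peak_db <- p_lo[peak_i]
  # dip between the component's peak and the main band
  gapband <- freq > f_lo[peak_i] & freq < main_low
  gap_db <- if (any(gapband)) peak_db - linear_to_db(min(p[gapband])) else 0
  list(present = excess[peak_i] >= config$lf_min_excess_db &&
         gap_db >= config$lf_gap_db,
       f0_hz = f_lo[peak_i], gap_db = gap_db)
}

#' Classify every selection of a clip
#'
#' Convenience wrapper running [measure_call()], [detect_pulses()],
#' [lf_component_evidence()] and [classify_call()] over a selection table.
#' The pulse-detection band is the selection's own frequency bounds when
#' present, otherwise the full analysed band.
#'
#' @param clip a `calibrated_clip`.
#' @param selections selection table (data.frame with `begin_s`, `end_s`,
#'   optionally `low_hz`, `high_hz`).
#' @param ambient_db ambient density reference below 20 kHz for biphonation
#'   evidence (see [lf_component_evidence()]).
#' @param config a [classifier_config()].
#' @return the selection table with a `class` column appended (or replaced).
#' @export
classify_selections <- function(clip, selections, ambient_db = NULL,
                                config = classifier_config()) {
  n <- nrow(selections)
  cls <- character(n)
  for (i in seq_len(n)) {
    sel <- selections[i, ]
    band_lo <- if (!is.null(sel$low_hz) && is.finite(sel$low_hz))
      max(sel$low_hz, 100) else 100
    band_hi <- if (!is.null(sel$high_hz) && is.finite(sel$high_hz))
      sel$high_hz else clip$fs / 2
    m <- measure_call(clip, sel)
    sub <- calibrated_clip(
      clip$pressure[(max(1L, floor(sel$begin_s * clip$fs) + 1L)):
                      (min(length(clip$pressure), ceiling(sel$end_s * clip$fs)))],
      clip$cal)
    train <- detect_pulses(sub, c(band_lo, band_hi))
    lf <- lf_component_evidence(clip, sel, ambient_db = ambient_db,
                                config = config)
    cls[i] <- classify_call(m, train, lf = lf, config = config)
  }
  selections$class <- cls
  selections
}
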