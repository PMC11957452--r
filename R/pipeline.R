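#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic experiment: how many
#' events, treatment durations, recorder calibration, ambient and vessel
#' specs (one rolloff per event, recycled), classifier thresholds, count
#' model parameters, and the master seed from which all per-event seeds are
#' derived.
#'
#' @param n_events number of synthetic noise events.
#' @param durations_s named numeric, seconds per treatment (<= 300 each).
#' @param fs sampling rate, Hz.
#' @param rolloff_hz vessel rolloff per event (recycled), Hz.
#' @param rates_per_min expected call-rate matrix (see
#'   [default_event_rates()]).
#' @param theta,event_sd count dispersion and between-event heterogeneity.
#' @param ambient an [ambient_spec()].
#' @param vessel_level_db,vessel_slope vessel spectrum parameters.
#' @param classifier a [classifier_config()].
#' @param uncertainty_db masking threshold shift for the lower bound, dB.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_events = 12,
                            durations_s = c(before = 30, during = 30, after = 30),
                            fs = 288000, rolloff_hz = 50000,
                            rates_per_min = default_event_rates(),
                            theta = 2, event_sd = 0.8,
                            ambient = ambient_spec(),
                            vessel_level_db = 95, vessel_slope = -10,
                            classifier = classifier_config(),
                            uncertainty_db = 3, seed = 1L) {
  .check(n_events >= 2, "need at least two events")
  .check(all(durations_s > 0 & durations_s <= 300),
         "treatment durations must lie in (0, 300] s")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full before/during/after experiment on synthetic events
#'
#' For each event: render the scene, extract call-free noise snippets per
#' treatment, estimate Welch spectra of the concatenated snippets, integrate
#' to one-third-octave bands, form the signal excess and the masking
#' frequency; classify the event's calls from the truth selection table and
#' count them. Events that produced no calls are dropped from the rate
#' analysis (and reported); the remaining counts feed the NB mixed model,
#' the Holm-adjusted treatment contrasts and the pseudo-R2 decomposition.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage tables and a
#'   machine-readable JSON report are written.
#' @return list of class `pipeline_report` with elements `masking`
#'   (per-event results and the summary), `classification` (selection tables
#'   with assigned classes), `rates` (count records, model, contrasts,
#'   pseudo-R2), `dropped_events`, `seed`, `config_hash`, and `log`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  .check(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  cal <- if (config$fs == 288000) soundtrap_hf300() else iclisten_hf()
  rolloffs <- rep(config$rolloff_hz, length.out = config$n_events)
  log <- character(0)
  masking_results <- list()
  excess_tables <- list()
  all_selections <- list()
  durations <- list()
  for (e in seq_len(config$n_events)) {
    ev_id <- sprintf("event%02d", e)
    spec <- event_spec(ev_id, rates_per_min = config$rates_per_min,
                       durations_s = config$durations_s, fs = config$fs,
                       theta = config$theta, event_sd = config$event_sd,
                       seed = config$seed + 1000L * e)
    vessel <- vessel_noise_spec(config$vessel_level_db, config$vessel_slope,
                                rolloff_hz = rolloffs[e],
                                duration_s = config$durations_s[["during"]])
    scene <- render_event(spec, vessel, cal, config$ambient)
    log <- c(log, scene$log)
    tol <- list()
    for (tr in c("before", "during", "after")) {
      sel_tr <- scene$truth[scene$truth$treatment == tr, ]
      snip <- extract_noise_snippets(scene$clips[[tr]], sel_tr)
      tol[[tr]] <- third_octave_levels(welch_ssdl(snip$noise))
    }
    exc <- signal_excess(tol$during, tol$before, tol$after)
    excess_tables[[ev_id]] <- exc
    masking_results[[ev_id]] <- masking_frequency(
      exc, uncertainty_db = config$uncertainty_db, event_id = ev_id)
    for (tr in c("before", "during", "after")) {
      sel_tr <- scene$truth[scene$truth$treatment == tr, ]
      if (nrow(sel_tr) > 0) {
        cls <- classify_selections(scene$clips[[tr]], sel_tr,
                                   config = config$classifier)
        cls$event_id <- ev_id
        all_selections[[length(all_selections) + 1]] <- cls
      }
    }
    durations[[ev_id]] <- data.frame(
      event_id = ev_id, treatment = c("before", "during", "after"),
      exposure_min = as.numeric(config$durations_s[c("before", "during", "after")]) / 60)
    log <- c(log, sprintf("%s: masking %s", ev_id,
                          if (masking_results[[ev_id]]$full_band) "full-band"
                          else sprintf("%.3g kHz", masking_results[[ev_id]]$f_down_hz / 1000)))
  }
  selections <- if (length(all_selections)) do.call(rbind, all_selections) else
    data.frame(event_id = character(0), treatment = character(0),
               class = character(0))
  durations <- do.call(rbind, durations)
  counts <- tabulate_rates(selections, durations)
  per_event <- tapply(counts$count, counts$event_id, sum)
  dropped <- names(per_event)[per_event == 0]
  if (length(dropped)) {
    log <- c(log, sprintf("dropped %d zero-call event(s): %s",
                          length(dropped), paste(dropped, collapse = ", ")))
    counts <- counts[!counts$event_id %in% dropped, ]
  }
  fit <- fit_nb_glmm(counts)
  contrasts <- pairwise_contrasts(fit)
  r2 <- pseudo_r2(fit)
  msum <- summarize_masking(masking_results)
  report <- structure(list(
    masking = list(per_event = masking_results, summary = msum,
                   excess = excess_tables),
    classification = selections,
    rates = list(counts = counts, fit = fit, contrasts = contrasts,
                 pseudo_r2 = r2),
    dropped_events = dropped,
    seed = config$seed,
    config_hash = .config_hash(config),
    log = log), class = "pipeline_report")
  if (!is.null(out_dir)) .write_report(report, config, out_dir)
  report
}

# stable short hash of the configuration (31-polynomial rolling hash of its
# deparse, kept inside 31-bit integer range)
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_report <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$config_hash <- report$config_hash; df$seed <- report$seed; df
  }
  exc <- do.call(rbind, lapply(names(report$masking$excess), function(ev) {
    cbind(event_id = ev, as.data.frame(report$masking$excess[[ev]]))
  }))
  utils::write.csv(stamp(exc), file.path(out_dir, "signal_excess.csv"),
                   row.names = FALSE)
  mk <- do.call(rbind, lapply(report$masking$per_event, function(r) {
    data.frame(event_id = r$event_id, f_down_hz = r$f_down_hz,
               f_down_lower_hz = r$f_down_lower_hz, full_band = r$full_band)
  }))
  utils::write.csv(stamp(mk), file.path(out_dir, "masking.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$rates$counts),
                   file.path(out_dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$rates$contrasts),
                   file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$rates$fit$fixed),
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    seed = report$seed, config_hash = report$config_hash,
    masking_summary = list(
      n = report$masking$summary$n,
      n_full_band = report$masking$summary$n_full_band,
      mean_khz = report$masking$summary$mean_hz / 1000,
      sd_khz = report$masking$summary$sd_hz / 1000,
      percentiles_khz = as.list(report$masking$summary$percentiles_hz / 1000)),
    pseudo_r2 = as.list(report$rates$pseudo_r2),
    dropped_events = report$dropped_events,
    n_calls = nrow(report$classification),
    log = report$log),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$masking$summary
  cat(sprintf("<pipeline_report> seed %s, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  masking: n=%d events (%d full-band), f_down %.3g +/- %.3g kHz\n",
              s$n, s$n_full_band, s$mean_hz / 1000, s$sd_hz / 1000))
  cat(sprintf("  calls: %d classified; %d event(s) dropped\n",
              nrow(x$classification), length(x$dropped_events)))
  cat(sprintf("  pseudo-R2: fixed %.1f%%, event %.1f%%, residual %.1f%%\n",
              x$rates$pseudo_r2[["marginal_pct"]],
              x$rates$pseudo_r2[["random_pct"]],
              x$rates$pseudo_r2[["residual_pct"]]))
  invisible(x)
}

#' Validate an event manifest
#'
#' Checks a manifest of noise events against the experimental-design rules:
#' every treatment at most 300 s (the 5-min cap), consecutive events
#' separated by more than `min_separation_s` (10 min by default), and any
#' referenced audio files present on disk.
#'
#' @param manifest data.frame with `event_id`, `start_s` (event start time on
#'   a common clock, s), treatment duration columns `before_s`, `during_s`,
#'   `after_s`, and optional `*_path` columns with audio file paths.
#' @param min_separation_s minimum separation between the end of one event
#'   and the start of the next, s.
#' @return data.frame of violations (`event_id`, `rule`, `detail`); zero
#'   rows when the manifest is compliant.
#' @export
validate_manifest <- function(manifest, min_separation_s = 600) {
  need <- c("event_id", "start_s", "before_s", "during_s", "after_s")
  .check(is.data.frame(manifest) && all(need %in% names(manifest)),
         "manifest must be a data.frame with %s", paste(need, collapse = ", "))
  v <- list()
  add <- function(ev, rule, detail) {
    v[[length(v) + 1]] <<- data.frame(event_id = ev, rule = rule, detail = detail)
  }
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    for (tr in c("before", "during", "after")) {
      d <- r[[paste0(tr, "_s")]]
      if (d > 300) add(r$event_id, "treatment_too_long",
                       sprintf("%s treatment is %.0f s (max 300)", tr, d))
    }
    for (col in grep("_path$", names(manifest), value = TRUE)) {
      p <- r[[col]]
      if (!is.na(p) && nzchar(p) && !file.exists(p)) {
        add(r$event_id, "missing_file", sprintf("%s: %s", col, p))
      }
    }
  }
  ord <- order(manifest$start_s)
  m <- manifest[ord, ]
  if (nrow(m) >= 2) {
    ends <- m$start_s + m$before_s + m$during_s + m$after_s
    gaps <- m$start_s[-1] - ends[-nrow(m)]
    for (i in which(gaps < min_separation_s)) {
      add(m$event_id[i + 1], "under_separated",
          sprintf("only %.0f s after %s (min %.0f)", gaps[i], m$event_id[i],
                  min_separation_s))
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(event_id = character(0), rule = character(0),
               detail = character(0))
}
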