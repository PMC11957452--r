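# Shared simulation helpers for the test suite.

# Count records at the analysis-type level (CC/HFBP/OTHER) for n_events,
# drawn straight from the event-count generator.
sim_type_records <- function(n_events, rates, theta = 2, event_sd = 0.8,
                             seed0 = 1, exposure_min = 5) {
  recs <- do.call(rbind, lapply(seq_len(n_events), function(e) {
    cnt <- sample_event_counts(event_spec(
      sprintf("e%03d", e), rates_per_min = rates,
      durations_s = c(before = exposure_min * 60, during = exposure_min * 60,
                      after = exposure_min * 60),
      theta = theta, event_sd = event_sd, seed = seed0 + e))
    cnt
  }))
  names(recs)[names(recs) == "call_class"] <- "call_type"
  recs
}

# Rates matrix at the analysis-type level emulating the observed pattern.
type_rates <- function() {
  during <- c(CC = 0.6, HFBP = 7.5, OTHER = 2.4)
  mult <- rbind(before = c(CC = exp(1.245), HFBP = exp(-0.294), OTHER = exp(1.097)),
                during = c(CC = 1, HFBP = 1, OTHER = 1),
                after = c(CC = exp(0.969), HFBP = exp(-0.124), OTHER = exp(1.149)))
  sweep(mult, 2, during, `*`)
}

# True fixed-effect vector implied by a per-minute rate matrix for the model
# count ~ treatment * call_type + offset(log exposure), treatment ref
# "during", call_type ref "CC". Solved exactly from the 9 cell log-rates.
beta_truth <- function(rates) {
  grid <- expand.grid(
    treatment = factor(c("during", "before", "after"),
                       levels = c("during", "before", "after")),
    call_type = factor(c("CC", "HFBP", "OTHER")))
  X <- stats::model.matrix(~ treatment * call_type, grid)
  eta <- log(rates[cbind(as.character(grid$treatment),
                         as.character(grid$call_type))])
  stats::setNames(drop(solve(X, eta)), colnames(X))
}

# A small rendered scene reused by classification tests (built once per run).
balanced_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rates <- matrix(6, 3, 5,
                      dimnames = list(c("before", "during", "after"),
                                      c("HFBP_M", "HFBP_B", "CC", "WHISTLE", "BUZZ")))
      rates[, "CC"] <- 3
      rates[, "BUZZ"] <- 2
      spec <- event_spec("scene1", rates_per_min = rates,
                         durations_s = c(before = 30, during = 30, after = 30),
                         theta = 1e6, event_sd = 0, seed = 5)
      cache <<- render_event(spec, vessel_noise_spec(rolloff_hz = 50000))
    }
    cache
  }
})
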