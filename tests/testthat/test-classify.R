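fs <- 288000
cal <- soundtrap_hf300()

# measurements/trains for rule-order tests without audio
fake_m <- function(low, high, dur) {
  structure(list(low_freq_khz = low, high_freq_khz = high, delta_time_s = dur,
                 delta_freq_khz = high - low, peak_freq_khz = (low + high) / 2,
                 center_freq_khz = (low + high) / 2,
                 q1_freq_khz = low + (high - low) / 4,
                 q3_freq_khz = low + 3 * (high - low) / 4),
            class = "call_measurements")
}
fake_train <- function(n = 100, rate = 350, cv = 0.05, slope = 0) {
  structure(list(pulse_times_s = seq(0, by = 1 / rate, length.out = n),
                 ipis_s = rep(1 / rate, max(n - 1, 0)), n_pulses = n,
                 rate_hz = if (n >= 2) rate else NA_real_,
                 ipi_cv = if (n >= 3) cv else NA_real_,
                 ipi_slope = if (n >= 4) slope else NA_real_),
            class = "pulse_train")
}

test_that("classification rules fire in their documented order", {
  # accelerating train is excluded before anything else
  expect_equal(classify_call(fake_m(40, 144, 0.4), fake_train(slope = -0.5)),
               "BUZZ_EXCLUDED")
  # a neighbouring click train within 1 s excludes an otherwise perfect HFBP
  expect_equal(classify_call(fake_m(40, 144, 0.4), fake_train(),
                             context = list(click_train_gap_s = 0.5)),
               "BUZZ_EXCLUDED")
  expect_equal(classify_call(fake_m(40, 144, 0.4), fake_train(),
                             context = list(click_train_gap_s = 5)),
               "HFBP_M")
  # biphonal evidence turns HFBP_M into HFBP_B
  expect_equal(classify_call(fake_m(40, 144, 0.4), fake_train(),
                             lf = list(present = TRUE)), "HFBP_B")
  # ultrasonic but with energy below 30 kHz and no low-frequency component
  expect_equal(classify_call(fake_m(22, 144, 0.4), fake_train()), "OTHER")
  # broadband long pulsed signal below the gate is a contact call
  expect_equal(classify_call(fake_m(0.2, 144, 1.2), fake_train(rate = 250)),
               "CC")
  # short broadband burst fails the duration floor
  expect_equal(classify_call(fake_m(0.2, 144, 0.2), fake_train(rate = 250)),
               "OTHER")
  # erratic train is not a consistent burst pulse
  expect_equal(classify_call(fake_m(40, 144, 0.4), fake_train(cv = 0.8)),
               "OTHER")
  # non-pulsed tonal content
  expect_equal(classify_call(fake_m(3, 18, 0.8), fake_train(n = 0)), "OTHER")
})

test_that("the classifier is deterministic", {
  m <- fake_m(40, 144, 0.4)
  tr <- fake_train()
  expect_identical(classify_call(m, tr), classify_call(m, tr))
})

test_that("quiet-treatment classification recovers every truth class", {
  scene <- balanced_scene()
  agg <- list()
  for (tr in c("before", "after")) {
    sel <- scene$truth[scene$truth$treatment == tr, ]
    cls <- classify_selections(scene$clips[[tr]], sel)
    agg[[tr]] <- data.frame(truth = sel$class, pred = cls$class)
  }
  r <- do.call(rbind, agg)
  expected <- c(HFBP_M = "HFBP_M", HFBP_B = "HFBP_B", CC = "CC",
                WHISTLE = "OTHER", BUZZ = "BUZZ_EXCLUDED")
  # recall and precision 1.0 per class at clean SNR
  expect_identical(unname(expected[r$truth]), r$pred)
  expect_gt(nrow(r), 10)
})

test_that("biphonation evidence finds a real LF component and not ambient", {
  set.seed(31)
  amb <- synth_ambient_noise(ambient_spec(), 0.5, fs)
  tm_b <- call_template("HFBP_B", 34000, 144000, 0.45, 135,
                        lf_component = list(f0_hz = 1500, bandwidth_hz = 1500,
                                            level_db = 126))
  x <- synth_call(tm_b, fs)
  clip_b <- calibrated_clip(amb[seq_along(x)] + x, cal)
  ev <- lf_component_evidence(clip_b, list(begin_s = 0, end_s = 0.45,
                                           low_hz = 34000))
  expect_true(ev$present)
  expect_lt(ev$f0_hz, 20000)
  expect_gte(ev$gap_db, 10)
  # monophonic call over the same ambient: no evidence
  tm_m <- call_template("HFBP_M", 36400, 144000, 0.45, 135)
  y <- synth_call(tm_m, fs, seed = 32)
  clip_m <- calibrated_clip(amb[seq_along(y)] + y, cal)
  ev_m <- lf_component_evidence(clip_m, list(begin_s = 0, end_s = 0.45,
                                             low_hz = 36400))
  expect_false(ev_m$present)
})

test_that("vessel noise masks the LF component so the call pools as HFBP_M", {
  set.seed(33)
  amb <- synth_ambient_noise(ambient_spec(), 0.5, fs)
  ves <- synth_vessel_noise(vessel_noise_spec(rolloff_hz = 50000), fs, 0.5)
  tm_b <- call_template("HFBP_B", 34000, 144000, 0.45, 135,
                        lf_component = list(f0_hz = 1500, bandwidth_hz = 1500,
                                            level_db = 126))
  x <- synth_call(tm_b, fs)
  clip <- calibrated_clip(amb[seq_along(x)] + ves[seq_along(x)] + x, cal)
  ev <- lf_component_evidence(clip, list(begin_s = 0, end_s = 0.45,
                                         low_hz = 34000))
  expect_false(ev$present)
  m <- measure_call(clip, list(begin_s = 0, end_s = 0.45, low_hz = 34000,
                               high_hz = 144000))
  sub <- detect_pulses(clip, c(34000, 144000))
  expect_equal(classify_call(m, sub, lf = ev), "HFBP_M")
})
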