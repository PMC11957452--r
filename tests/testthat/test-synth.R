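fs <- 288000
cal <- soundtrap_hf300()

test_that("call templates enforce their class invariants", {
  expect_error(call_template("HFBP_M", 36400, 144000, 0), "positive")
  expect_error(call_template("HFBP_M", 15000, 144000, 0.4, 135), "20 kHz")
  expect_error(call_template("BUZZ", 33000, 144000, 0.5, 130, ipi_trend = 0.1),
               "ipi_trend")
  expect_error(call_template("HFBP_B", 34000, 144000, 0.4, 135), "lf_component")
  expect_error(call_template("HFBP_B", 34000, 144000, 0.4, 135,
                             lf_component = list(f0_hz = 30000, bandwidth_hz = 10000)),
               "gap")
  tm <- call_template("HFBP_M", 36400, 144000, 0.4, 135)
  expect_error(synth_call(tm, 144000), "Nyquist")  # band above fs/2
  short <- call_template("HFBP_M", 36400, 144000, 0.004, 135)
  expect_error(synth_call(short, fs), "inter-pulse")
})

test_that("synthesised calls hit their RMS level and stay in their band", {
  tm <- call_template("HFBP_M", 36400, 144000, 0.4, 135)
  x <- synth_call(tm, fs, seed = 3)
  expect_equal(20 * log10(sqrt(mean(x^2))), 135, tolerance = 1)
  # spectral energy outside the band at least 30 dB below the in-band density
  p <- Mod(fft(x * (0.5 - 0.5 * cos(2 * pi * seq_along(x) / length(x)))))^2
  f <- belugamask:::.fft_freqs(length(x), fs)
  half <- seq_len(length(x) %/% 2)
  inband <- mean(p[half][f[half] >= 36400 & f[half] <= 144000])
  margin_lo <- f[half] < 36400 - 2000 & f[half] > 100
  expect_lt(10 * log10(max(p[half][margin_lo]) / inband), -30)
})

test_that("a measured clean burst-pulse call recovers its template band", {
  tm <- call_template("HFBP_M", 36400, 144000, 0.4, 135)
  x <- synth_call(tm, fs, seed = 4)
  m <- measure_call(calibrated_clip(x, cal),
                    list(begin_s = 0, end_s = length(x) / fs))
  # the automated edge sits within ~1 spectral bin (0.28 kHz) of the template
  expect_equal(m$low_freq_khz, 36.4, tolerance = 0.5)
  expect_identical(m$high_freq_khz, 144)
  expect_equal(m$delta_time_s, 0.4)
})

test_that("an accelerating buzz yields decreasing inter-pulse intervals", {
  tm <- call_template("BUZZ", 33000, 144000, 0.6, 130,
                      pulse_rate_hz = 120, ipi_trend = -0.8,
                      ipi_jitter_cv = 0)
  set.seed(5)
  times <- belugamask:::.pulse_times(tm)
  ipis <- diff(times)
  expect_true(all(diff(ipis) < 0))
  # and the detector sees the acceleration on the rendered audio
  x <- synth_call(tm, fs, seed = 5)
  tr <- detect_pulses(calibrated_clip(x, cal), c(33000, 144000))
  expect_lt(tr$ipi_slope, -0.3)
})

test_that("vessel noise matches its target spectrum band by band", {
  spec <- vessel_noise_spec(60, 0, rolloff_hz = 144000, ref_hz = 1000)
  v <- synth_vessel_noise(spec, fs, duration_s = 5, seed = 6)
  tol <- third_octave_levels(welch_ssdl(calibrated_clip(v, cal)))
  # flat density: every band within 1.5 dB of L + 10log10(width)
  expect_true(all(abs(tol$level_db - (60 + 10 * log10(tol$n_bins))) < 1.5))
})

test_that("white noise at sigma=1000 uPa gives the 8.42 dB density oracle", {
  set.seed(8)
  clip <- calibrated_clip(rnorm(5 * fs, sd = 1000), cal)
  s <- welch_ssdl(clip)
  expect_equal(linear_to_db(mean(db_to_linear(s$level_db))),
               10 * log10(1000^2 / (fs / 2)), tolerance = 0.5)
  expect_equal(10 * log10(1000^2 / (fs / 2)), 8.42, tolerance = 0.005)
})

test_that("a full-bandwidth vessel dominates every band (no rolloff case)", {
  amb <- ambient_spec()
  spec <- vessel_noise_spec(95, -10, rolloff_hz = 144000)
  set.seed(9)
  a1 <- synth_ambient_noise(amb, 5, fs)
  a2 <- synth_ambient_noise(amb, 5, fs)
  d <- synth_ambient_noise(amb, 5, fs) + synth_vessel_noise(spec, fs, 5)
  tol <- lapply(list(d, a1, a2), function(x)
    third_octave_levels(welch_ssdl(calibrated_clip(x, cal))))
  ex <- signal_excess(tol[[1]], tol[[2]], tol[[3]])
  expect_true(all(ex$delta_db > 0.05))
  expect_true(masking_frequency(ex)$full_band)
})

test_that("event counts are negative binomial with a shared event intercept", {
  rates <- matrix(6, 3, 2, dimnames = list(c("before", "during", "after"),
                                           c("HFBP_M", "CC")))
  # theta large, no heterogeneity: Poisson mean check over many draws
  mu <- 6 * 5  # rate * minutes
  draws <- vapply(1:1000, function(i) {
    cnt <- sample_event_counts(event_spec("e", rates_per_min = rates,
                                          theta = 1e9, event_sd = 0, seed = i))
    cnt$count[1]
  }, numeric(1))
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 1000))
  # identical seeds give identical counts
  s <- event_spec("e", rates_per_min = rates, seed = 42)
  expect_identical(sample_event_counts(s), sample_event_counts(s))
  # zero rates give all-zero counts
  z <- sample_event_counts(event_spec("e", rates_per_min = rates * 0, seed = 1))
  expect_true(all(z$count == 0))
})

test_that("event specs validate durations, rates and sampling rates", {
  expect_error(event_spec(durations_s = c(before = 400, during = 300, after = 300)),
               "300")
  expect_error(event_spec(fs = 44100), "fs")
  expect_error(event_spec(theta = 0), "theta")
})

test_that("rendered scenes are deterministic and internally consistent", {
  rates <- matrix(2, 3, 2, dimnames = list(c("before", "during", "after"),
                                           c("HFBP_M", "WHISTLE")))
  spec <- event_spec("det", rates_per_min = rates,
                     durations_s = c(before = 8, during = 8, after = 8),
                     seed = 21)
  vs <- vessel_noise_spec(rolloff_hz = 40000, duration_s = 8)
  s1 <- render_event(spec, vs)
  s2 <- render_event(spec, vs)
  expect_identical(s1$clips$during$pressure, s2$clips$during$pressure)
  expect_identical(s1$truth, s2$truth)
  # truth selections lie inside their clips; counts match selections per class
  for (tr in c("before", "during", "after")) {
    sel <- s1$truth[s1$truth$treatment == tr, ]
    dur <- length(s1$clips[[tr]]$pressure) / fs
    expect_true(all(sel$begin_s >= 0 & sel$end_s <= dur))
    cnt <- s1$counts[s1$counts$treatment == tr, ]
    for (cl in cnt$call_class) {
      expect_equal(sum(sel$class == cl), cnt$count[cnt$call_class == cl])
    }
  }
  # no digital clipping at default levels
  for (tr in names(s1$clips)) {
    expect_lt(max(abs(pressure_to_wav(s1$clips[[tr]]))), 1)
  }
})

test_that("a scene round-trips through its on-disk form", {
  rates <- matrix(2, 3, 1, dimnames = list(c("before", "during", "after"),
                                           "HFBP_M"))
  spec <- event_spec("disk", rates_per_min = rates,
                     durations_s = c(before = 6, during = 6, after = 6),
                     seed = 33)
  scene <- render_event(spec, vessel_noise_spec(rolloff_hz = 40000, duration_s = 6))
  dir <- withr::local_tempdir()
  paths <- write_scene(scene, dir)
  w <- read_wav(paths$before)
  expect_equal(w$fs, fs)
  back <- wav_to_pressure(w, cal)
  rms_db <- function(p) 10 * log10(mean(p^2))
  expect_lt(abs(rms_db(back$pressure) - rms_db(scene$clips$before$pressure)), 0.1)
  truth <- read_selection_table(paths$truth)
  expect_equal(nrow(truth), nrow(scene$truth))
  expect_equal(truth$begin_s, scene$truth$begin_s, tolerance = 1e-6)
  man <- yaml::read_yaml(paths$manifest)
  expect_equal(man$seed, 33)
  expect_equal(man$vessel_rolloff_hz, 40000)
})
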