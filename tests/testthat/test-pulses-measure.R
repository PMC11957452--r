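fs <- 288000
cal <- soundtrap_hf300()

# a bare train of Hann transients at given pulse times (s)
raw_train <- function(times, fs, dur_s, pulse_len_s = 3e-4, band = c(30000, 120000)) {
  n <- round(dur_s * fs)
  np <- round(pulse_len_s * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(np) - 1) / (np - 1))
  x <- numeric(n)
  for (tt in times) {
    i0 <- round(tt * fs) + 1L
    idx <- i0:min(i0 + np - 1L, n)
    x[idx] <- x[idx] + win[seq_along(idx)] * rnorm(length(idx))
  }
  belugamask:::.fft_bandpass(x, fs, band[1], band[2])
}

test_that("silence yields an empty train", {
  tr <- detect_pulses(calibrated_clip(numeric(fs %/% 10), cal), c(30000, 120000))
  expect_equal(tr$n_pulses, 0)
  expect_true(is.na(tr$rate_hz))
})

test_that("a constant-rate train is recovered with its rate and tiny IPI cv", {
  set.seed(1)
  times <- (0:9) / 100  # 10 pulses at 100 pulses/s
  x <- raw_train(times, fs, 0.105)
  tr <- detect_pulses(calibrated_clip(x * 1000, cal), c(30000, 120000))
  expect_equal(tr$n_pulses, 10)
  expect_equal(tr$rate_hz, 100, tolerance = 0.02)
  expect_lt(tr$ipi_cv, 0.02)
  # detected peaks sit inside their transients (within half a pulse length)
  expect_lt(max(abs(tr$pulse_times_s - times)), 3.5e-4)
})

test_that("an accelerating train has a negative IPI slope", {
  set.seed(2)
  # IPI shrinking 20 ms -> 2 ms
  ipis <- seq(0.02, 0.002, length.out = 30)
  times <- cumsum(c(0, ipis))
  x <- raw_train(times, fs, max(times) + 0.01)
  tr <- detect_pulses(calibrated_clip(x * 1000, cal), c(30000, 120000))
  expect_lt(tr$ipi_slope, 0)
  # regression oracle on the emitted times themselves
  fit <- lsfit(times[-length(times)], diff(times))
  expect_lt(fit$coefficients[2], 0)
})

test_that("detect_pulses validates its band", {
  clip <- calibrated_clip(numeric(1000), cal)
  expect_error(detect_pulses(clip, c(200000, 100000)), "band")
  expect_error(detect_pulses(clip, c(10000, 200000)), "band")
})

test_that("a flat-spectrum band yields the analytic quantile frequencies", {
  set.seed(3)
  x <- belugamask:::.shaped_noise(fs, fs, function(f)
    ifelse(f >= 36400 & f <= 144000, 40, -Inf))
  m <- measure_call(calibrated_clip(x, cal), list(begin_s = 0, end_s = 1))
  # uniform density on [36.4, 144]: quantiles at 36.4 + q * 107.6
  expect_equal(m$q1_freq_khz, 36.4 + 0.25 * 107.6, tolerance = 1)
  expect_equal(m$center_freq_khz, 36.4 + 0.50 * 107.6, tolerance = 1)
  expect_equal(m$q3_freq_khz, 36.4 + 0.75 * 107.6, tolerance = 1)
  expect_equal(m$low_freq_khz, 36.4, tolerance = 0.5)
  expect_identical(m$high_freq_khz, 144)
  expect_equal(m$delta_freq_khz, m$high_freq_khz - m$low_freq_khz)
})

test_that("a pure tone collapses all frequency measures onto the tone", {
  t <- (1:(fs %/% 2)) / fs
  x <- 1e3 * sin(2 * pi * 50000 * t)
  m <- measure_call(calibrated_clip(x, cal), list(begin_s = 0, end_s = 0.5))
  expect_equal(m$peak_freq_khz, 50, tolerance = 0.3)
  expect_equal(m$center_freq_khz, 50, tolerance = 0.3)
  expect_equal(m$q1_freq_khz, 50, tolerance = 0.3)
  expect_equal(m$q3_freq_khz, 50, tolerance = 0.3)
})

test_that("quantiles match a cumulative-sum oracle on the raw periodogram", {
  set.seed(4)
  # shaped two-band spectrum
  x <- belugamask:::.shaped_noise(fs, fs, function(f)
    ifelse(f >= 30000 & f <= 60000, 46,
           ifelse(f >= 90000 & f <= 130000, 40, -Inf)))
  clip <- calibrated_clip(x, cal)
  m <- measure_call(clip, list(begin_s = 0, end_s = 1))
  # oracle: brute-force cumulative sum over the same Welch spectrum
  nfft <- 1024
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  starts <- seq(1, length(x) - nfft + 1, by = nfft / 2)
  p <- rowMeans(vapply(starts, function(s)
    Mod(fft(x[s:(s + nfft - 1)] * w)[1:(nfft / 2 + 1)])^2, numeric(nfft / 2 + 1)))
  freq <- (0:(nfft / 2)) * fs / nfft
  above <- which(p >= max(p) * 10^(-20 / 10))
  supp <- above[1]:above[length(above)]
  cs <- cumsum(p[supp]) / sum(p[supp])
  bin <- fs / nfft / 1000
  expect_equal(m$q1_freq_khz, freq[supp[which(cs >= 0.25)[1]]] / 1000,
               tolerance = bin)
  expect_equal(m$center_freq_khz, freq[supp[which(cs >= 0.5)[1]]] / 1000,
               tolerance = bin)
  expect_equal(m$q3_freq_khz, freq[supp[which(cs >= 0.75)[1]]] / 1000,
               tolerance = bin)
})

test_that("frequency measurements are always ordered low <= q1 <= center <= q3 <= high", {
  set.seed(5)
  for (rep in 1:12) {
    lo <- runif(1, 1000, 60000)
    hi <- lo + runif(1, 5000, 80000)
    slope <- runif(1, -20, 20)
    x <- belugamask:::.shaped_noise(fs %/% 2, fs, function(f)
      ifelse(f >= lo & f <= hi, 40 + slope * log10(pmax(f, 1) / lo), -Inf)) +
      rnorm(fs %/% 2, sd = 0.1)
    m <- measure_call(calibrated_clip(x, cal), list(begin_s = 0, end_s = 0.5))
    expect_true(m$low_freq_khz <= m$q1_freq_khz)
    expect_true(m$q1_freq_khz <= m$center_freq_khz)
    expect_true(m$center_freq_khz <= m$q3_freq_khz)
    expect_true(m$q3_freq_khz <= m$high_freq_khz)
    expect_gt(m$delta_time_s, 0)
  }
})

test_that("degenerate selections are rejected", {
  clip <- calibrated_clip(rnorm(1000), cal)
  expect_error(measure_call(clip, list(begin_s = 0.5, end_s = 0.5)), "begin_s")
  expect_error(measure_call(clip, list(begin_s = 0, end_s = 0.001,
                                       low_hz = 1000, high_hz = 500000)),
               "Nyquist")
})
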