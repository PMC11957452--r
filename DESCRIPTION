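Package: belugamask
Title: Vessel-Noise Masking and Ultrasonic Call-Rate Analysis for Beluga
    Acoustics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether ultrasonic high-frequency burst-pulse
    (HFBP) calls give beluga whales a communication channel that escapes vessel
    noise. Provides calibrated conversion of hydrophone recordings to pressure,
    Welch sound-spectral-density levels and base-10 one-third-octave band
    levels, a per-band signal-excess statistic with a masking-frequency
    estimator, rule-based classification and Raven-style measurement of
    burst-pulse calls, negative-binomial mixed-model inference on call rates
    across before/during/after vessel exposure, and a fully synthetic
    soundscape generator (ambient bed, shaped vessel noise, parametric call
    templates) so the entire pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    emmeans,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
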