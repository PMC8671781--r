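test_that("band_power integrates flat, zero and bump spectra correctly", {
  expect_equal(band_power(flat_psd(2), 0, 15), 30)
  expect_equal(band_power(flat_psd(0), 0, 15), 0)
  # Gaussian bump fully inside the band: integral nearly all captured
  f <- seq(0, 100, by = 0.25)
  bump <- exp(-(f - 50)^2 / (2 * 4^2))
  ps <- psd_from_curve(f, bump)
  total <- sum((bump[-1] + bump[-length(f)]) / 2 * diff(f))
  expect_gte(band_power(ps, 30, 70) / total, 0.99)
  expect_error(band_power(flat_psd(1, fs = 100), 0, 60), "outside")
  expect_error(band_power(flat_psd(1), 10, 10), "outside")
})

test_that("band_power is additive at interior grid points", {
  set.seed(9)
  f <- seq(0, 100, by = 0.5)
  for (i in 1:10) {
    p <- abs(rnorm(length(f)))
    ps <- psd_from_curve(f, p)
    b <- sample(f[f > 10 & f < 90], 1)
    expect_equal(band_power(ps, 5, b) + band_power(ps, b, 95),
                 band_power(ps, 5, 95), tolerance = 1e-12)
  }
})

test_that("detect_flapband_peak finds in-band maxima and ignores others", {
  f <- seq(0, 100, by = 0.5)
  bump <- function(c0, w = 1.5) exp(-(f - c0)^2 / (2 * w^2))
  one <- psd_from_curve(f, bump(25))
  pk <- detect_flapband_peak(one)
  expect_lt(abs(pk$freq - 25), 0.5)
  expect_gte(pk$prominence, 1)
  # strictly decreasing spectrum: no interior maximum
  expect_null(detect_flapband_peak(psd_from_curve(f, 100 - f)))
  # out-of-band bump at 10 Hz plus in-band bump at 25: the in-band one wins
  two <- psd_from_curve(f, 5 * bump(10) + bump(25))
  expect_lt(abs(detect_flapband_peak(two)$freq - 25), 0.5)
})

test_that("spectral_features and classify_state implement the decision rule", {
  mk <- function(prom, fluct, low) {
    structure(list(lowband_power = low,
                   flapband_peak_freq = if (is.na(prom)) NA_real_ else 25,
                   flapband_peak_prominence = prom,
                   fluctuation_score = fluct, state_call = NA_character_,
                   state_truth = "unknown"),
              class = "spectral_features")
  }
  th <- state_thresholds()  # prominence 1.5, fluctuation 3, ratio 1.3
  # peak absent and no fluctuation -> calm
  expect_equal(classify_state(mk(NA, 0, 1))$state_call, "calm")
  # peak + fluctuation clause
  expect_equal(classify_state(mk(2, 3, 1))$state_call, "flapping")
  expect_equal(classify_state(mk(2, 2, 1))$state_call, "calm")
  # peak + ratio clause
  expect_equal(classify_state(mk(2, 0, 13), calm_lowband = 10)$state_call,
               "flapping")
  expect_equal(classify_state(mk(2, 0, 12), calm_lowband = 10)$state_call,
               "calm")
  # prominence below threshold blocks everything
  expect_equal(classify_state(mk(1.4, 5, 13), calm_lowband = 10)$state_call,
               "calm")
  # deterministic
  expect_identical(classify_state(mk(2, 3, 1))$state_call,
                   classify_state(mk(2, 3, 1))$state_call)
  # ratio clause enabled without a reference is a configuration error
  expect_error(classify_state(mk(2, 0, 13), use_lowband_ratio = TRUE),
               "calm")
  # decision record is attached
  out <- classify_state(mk(2, 3, 1), thresholds = th)
  expect_true(out$decision$peak_ok)
  expect_true(out$decision$fluct_ok)
})

test_that("synthetic flapping and calm traces classify to their true labels", {
  ref <- ar_psd(burg_ar(preprocess_trace(
    generate_lfp(lfp_gen_config(seed = 901), "calm"))))
  calm_ref <- band_power(ref, 0, 15)
  for (sd in c(7, 23)) {
    for (st in c("flapping", "calm")) {
      ps <- ar_psd(burg_ar(preprocess_trace(
        generate_lfp(lfp_gen_config(seed = sd), st))))
      fe <- classify_state(spectral_features(ps), calm_lowband = calm_ref)
      expect_equal(fe$state_call, st)
      expect_equal(fe$state_truth, st)
    }
  }
})

test_that("find_transition_frequency locates the positive-to-negative crossing", {
  f <- seq(0, 100, by = 0.5)
  base <- avg_from_curve(f, rep(10, length(f)))
  # constant offset: no crossing
  up <- avg_from_curve(f, rep(11, length(f)))
  expect_null(find_transition_frequency(up, base))
  # difference 30 - f: crossing at exactly 30 Hz
  lin <- avg_from_curve(f, 10 + (30 - f))
  expect_equal(find_transition_frequency(lin, base), 30)
  # negative-to-positive only: not a flapping-style crossing
  rev <- avg_from_curve(f, 10 + (f - 30))
  expect_null(find_transition_frequency(rev, base))
  expect_error(find_transition_frequency(up, avg_from_curve(f / 2, rep(1, length(f)))),
               "grid")
})
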