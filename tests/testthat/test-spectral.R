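test_that("burg_ar reproduces the closed-form first lattice stage", {
  fit <- suppressWarnings(burg_ar(lfp_trace(c(1, 1), 100), order = 1))
  expect_equal(fit$reflection, -1)
  expect_equal(fit$coefficients, -1)
  expect_equal(fit$noise_variance, 0)
})

test_that("burg_ar handles degenerate input and bad orders", {
  z <- burg_ar(lfp_trace(rep(0, 64), 100), order = 4)
  expect_equal(z$coefficients, rep(0, 4))
  expect_equal(z$noise_variance, 0)
  expect_error(burg_ar(lfp_trace(rnorm(10), 100), order = 10), "order")
  expect_error(burg_ar(lfp_trace(rnorm(10), 100), order = 0), "order")
  expect_warning(burg_ar(lfp_trace(rnorm(64) + 10, 100), order = 2), "DC-free")
})

test_that("burg_ar agrees with a brute-force lattice oracle to 1e-10", {
  for (sd in 1:20) {
    set.seed(sd)
    n <- sample(8:64, 1)
    p <- sample(1:4, 1)
    x <- as.numeric(arima.sim(list(ar = 0.4), n))
    fit <- burg_ar(lfp_trace(x - mean(x), 100), order = p)
    oracle <- burg_brute(x - mean(x), p)
    expect_equal(fit$coefficients, oracle$a, tolerance = 1e-10)
    expect_equal(fit$reflection, oracle$k, tolerance = 1e-10)
    expect_equal(fit$noise_variance, oracle$var, tolerance = 1e-10)
  }
})

test_that("burg_ar matches stats::ar.burg up to the sign convention", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 1024))
  x <- x - mean(x)
  fit <- burg_ar(lfp_trace(x, 100), order = 2)
  ref <- stats::ar.burg(x, aic = FALSE, order.max = 2, demean = FALSE)
  expect_equal(fit$coefficients, -as.numeric(ref$ar), tolerance = 1e-6)
})

test_that("burg_ar recovers generating AR coefficients", {
  set.seed(7)
  x <- as.numeric(arima.sim(list(ar = 0.5), 4096))
  fit <- burg_ar(lfp_trace(x - mean(x), 100), order = 1)
  expect_gt(fit$coefficients[1], -0.55)
  expect_lt(fit$coefficients[1], -0.45)
  # white noise: all 15 coefficients near zero
  set.seed(8)
  w <- rnorm(4096)
  fitw <- burg_ar(lfp_trace(w - mean(w), 100), order = 15)
  expect_lt(max(abs(fitw$coefficients)), 0.1)
  expect_true(all(abs(fitw$reflection) <= 1))
})

test_that("ar_psd has the stated grid, white-noise and pole-placement behavior", {
  mdl <- structure(list(order = 0, coefficients = numeric(0),
                        reflection = numeric(0), noise_variance = 2,
                        sampling_rate = 1000, n = 100, state = "unknown",
                        meta = list()),
                   class = "ar_model")
  ps <- ar_psd(mdl, nfft = 1024)
  expect_length(ps$frequencies, 513)
  expect_equal(ps$frequencies[1], 0)
  expect_equal(ps$frequencies[513], 500)
  # flat across interior bins (one-sided doubling applies there uniformly)
  expect_equal(diff(range(ps$power[2:512])), 0)
  expect_equal(ps$power[2], 2 * ps$power[1])

  # AR(1), a1 = -0.9: monotone decreasing spectrum, argmax at 0 Hz
  m1 <- structure(list(order = 1, coefficients = -0.9, reflection = -0.9,
                       noise_variance = 1, sampling_rate = 1000, n = 100,
                       state = "unknown", meta = list()),
                  class = "ar_model")
  p1 <- ar_psd(m1, nfft = 1024)
  # low-pass shape: strictly decreasing over the interior bins, and the DC
  # bin dominates once the one-sided doubling is undone
  expect_true(all(diff(p1$power[-1]) < 0))
  expect_gt(2 * p1$power[1], p1$power[2])

  # AR(2) with conjugate poles at 25 Hz
  fs <- 1000
  r <- 0.98
  th <- 2 * pi * 25 / fs
  a <- c(-2 * r * cos(th), r^2)   # x_t + a1 x_{t-1} + a2 x_{t-2} = e_t
  m2 <- structure(list(order = 2, coefficients = a, reflection = c(0, 0),
                       noise_variance = 1, sampling_rate = fs, n = 100,
                       state = "unknown", meta = list()),
                  class = "ar_model")
  p2 <- ar_psd(m2, nfft = 1024)
  expect_lt(abs(p2$frequencies[which.max(p2$power)] - 25), fs / 1024)
})

test_that("ar_psd refuses unstable models and bad nfft", {
  bad <- structure(list(order = 1, coefficients = -1.2, reflection = -1.2,
                        noise_variance = 1, sampling_rate = 100, n = 10,
                        state = "unknown", meta = list()),
                   class = "ar_model")
  expect_error(ar_psd(bad), "unstable")
  ok <- structure(list(order = 8, coefficients = rep(0, 8),
                       reflection = rep(0, 8), noise_variance = 1,
                       sampling_rate = 100, n = 10, state = "unknown",
                       meta = list()),
                  class = "ar_model")
  expect_error(ar_psd(ok, nfft = 8), "nfft")
  expect_warning(ar_psd(ok, nfft = 100), "power of two")
})

test_that("the one-sided AR spectrum approximately integrates to the variance", {
  for (sd in 1:5) {
    set.seed(sd)
    x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 4096))
    x <- x - mean(x)
    ps <- ar_psd(burg_ar(lfp_trace(x, 1000), order = 4), nfft = 1024)
    integral <- band_power(ps, 0, 500)
    expect_lt(abs(integral / var(x) - 1), 0.2)
  }
})

test_that("average_psd computes pointwise means and errors", {
  fs <- 1000
  set.seed(3)
  mk <- function(x) ar_psd(burg_ar(lfp_trace(x - mean(x), fs), order = 4))
  a <- mk(as.numeric(arima.sim(list(ar = 0.5), 512)))
  b <- mk(as.numeric(arima.sim(list(ar = 0.5), 512)))
  same <- average_psd(list(a, a, a))
  expect_equal(same$mean_power, a$power)
  expect_equal(same$error, rep(0, length(a$power)))

  ab <- average_psd(list(a, b))
  expect_equal(ab$mean_power, (a$power + b$power) / 2)
  expect_equal(ab$error, apply(cbind(a$power, b$power), 1, sd))
  sem <- average_psd(list(a, b), error_kind = "SEM")
  expect_equal(sem$error, ab$error / sqrt(2))

  # two simple spectra: powers 1 and 3 at a bin -> mean 2, SD sqrt(2)
  f1 <- flat_psd(1)
  f3 <- flat_psd(3)
  m <- average_psd(list(f1, f3))
  expect_equal(m$mean_power[10], 2)
  expect_equal(m$error[10], sqrt(2))

  mismatched <- flat_psd(1, fs = 100, nfft = 400)
  expect_error(average_psd(list(f1, mismatched)), "grid")
})
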