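# Independent oracles, deliberately sharing no code with R/.

# Band power by direct discrete-Fourier periodogram (sum over bins in band).
perio_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / (n * fs)
  f <- (0:(n - 1)) * fs / n
  sum(P[f >= lo & f <= hi & f <= fs / 2])
}

# Brute-force Burg lattice: direct scalar loops, textbook indexing.
burg_brute <- function(x, order) {
  n <- length(x)
  f <- x
  b <- x
  a <- c()
  E <- sum(x^2) / n
  ks <- numeric(order)
  for (m in 1:order) {
    num <- 0
    den <- 0
    for (t in (m + 1):n) {
      num <- num + f[t] * b[t - 1]
      den <- den + f[t]^2 + b[t - 1]^2
    }
    k <- if (den > 0) -2 * num / den else 0
    ks[m] <- k
    a_new <- numeric(m)
    if (m > 1) {
      for (i in 1:(m - 1)) a_new[i] <- a[i] + k * a[m - i]
    }
    a_new[m] <- k
    a <- a_new
    f_old <- f
    b_old <- b
    for (t in n:(m + 1)) {
      f[t] <- f_old[t] + k * b_old[t - 1]
      b[t] <- b_old[t - 1] + k * f_old[t]
    }
    E <- E * (1 - k^2)
  }
  list(a = a, k = ks, var = E)
}

# Brute-force Pearson correlation from the definition.
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

make_tone <- function(freq, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(fs * dur) - 1)) / fs + phase)
}

# Flat-spectrum psd_estimate for feature tests.
flat_psd <- function(height, fs = 200, nfft = 400) {
  nh <- nfft %/% 2
  structure(
    list(frequencies = (0:nh) * fs / nfft,
         power = rep(height, nh + 1), nfft = nfft,
         sampling_rate = fs, state = "unknown", meta = list()),
    class = "psd_estimate"
  )
}

psd_from_curve <- function(frequencies, power, state = "unknown") {
  structure(
    list(frequencies = frequencies, power = power,
         nfft = 2 * (length(frequencies) - 1),
         sampling_rate = 2 * max(frequencies), state = state, meta = list()),
    class = "psd_estimate"
  )
}

avg_from_curve <- function(frequencies, power, state = "unknown") {
  structure(
    list(frequencies = frequencies, mean_power = power,
         error = rep(0, length(frequencies)), n_samples = 1,
         error_kind = "SD", sampling_rate = 2 * max(frequencies),
         state = state),
    class = "avg_psd"
  )
}
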