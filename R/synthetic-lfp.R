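#' Configuration for the synthetic LFP generator
#'
#' Describes the statistical structure of a simulated optic-lobe LFP trace:
#' a DC offset, baseline wander concentrated near `baseline_freq` (a sinusoid
#' with random phase plus a small random-walk component), a 1/f^beta shaped
#' Gaussian background, and -- in the flapping state only -- a narrow-band
#' oscillation whose instantaneous frequency wanders inside `flap_band`
#' together with a redistribution of background power toward the low band.
#'
#' In the flapping state the background power is multiplied by
#' `lowband_boost` below `lowband_hi` and by `highband_suppress` above the
#' upper flapping-band edge (it is unchanged between the two). This encodes
#' the spectral redistribution between flight and rest -- low-band power up,
#' high-band power down -- and guarantees the state-average spectra cross at
#' some transition frequency between the two regions.
#'
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the upper
#'   flapping-band edge.
#' @param duration_s Trace duration in seconds.
#' @param dc_offset DC offset in microvolts.
#' @param baseline_freq Center frequency of the baseline wander (Hz).
#' @param baseline_amp Amplitude of the baseline-wander sinusoid (uV); the
#'   accompanying random-walk component has RMS `0.2 * baseline_amp`.
#' @param background_exponent Spectral exponent beta of the 1/f^beta
#'   background (unitless).
#' @param background_amp RMS amplitude of the shaped background (uV).
#' @param flap_band Length-2 numeric, the flapping oscillation band (Hz).
#' @param flap_osc_amp Amplitude of the flapping-state oscillation (uV).
#' @param lowband_boost Multiplier on background power below `lowband_hi`
#'   in the flapping state (unitless, >= 0); see Details.
#' @param lowband_hi Upper edge of the boosted low band (Hz).
#' @param highband_suppress Multiplier on background power above the upper
#'   flapping-band edge in the flapping state (unitless, >= 0); see Details.
#' @param seed Integer seed; identical config + state give bit-identical
#'   traces.
#'
#' @return A list of class `lfp_gen_config`.
#' @seealso [generate_lfp()]
#' @export
lfp_gen_config <- function(sampling_rate = 1000, duration_s = 10,
                           dc_offset = 20, baseline_freq = 0.7,
                           baseline_amp = 30, background_exponent = 1,
                           background_amp = 10, flap_band = c(20, 30),
                           flap_osc_amp = 40, lowband_boost = 6,
                           lowband_hi = 15, highband_suppress = 0.3,
                           seed = 1) {
  cfg <- list(sampling_rate = sampling_rate, duration_s = duration_s,
              dc_offset = dc_offset, baseline_freq = baseline_freq,
              baseline_amp = baseline_amp,
              background_exponent = background_exponent,
              background_amp = background_amp, flap_band = as.numeric(flap_band),
              flap_osc_amp = flap_osc_amp, lowband_boost = lowband_boost,
              lowband_hi = lowband_hi, highband_suppress = highband_suppress,
              seed = seed)
  validate_lfp_gen_config(cfg)
  structure(cfg, class = "lfp_gen_config")
}

validate_lfp_gen_config <- function(cfg) {
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0) {
    stop_invalid("duration_s must be positive")
  }
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate <= 0) {
    stop_invalid("sampling_rate must be positive")
  }
  if (length(cfg$flap_band) != 2L || cfg$flap_band[1] >= cfg$flap_band[2] ||
      cfg$flap_band[1] <= 0) {
    stop_invalid("flap_band must be an increasing positive pair (lo, hi) in Hz")
  }
  if (cfg$sampling_rate <= 2 * cfg$flap_band[2]) {
    stop_invalid("sampling_rate must exceed 2 * flap_band upper edge (Nyquist)")
  }
  amps <- c(cfg$baseline_amp, cfg$background_amp, cfg$flap_osc_amp,
            cfg$lowband_boost, cfg$highband_suppress)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop_invalid("amplitudes, lowband_boost and highband_suppress must be ",
                 "finite and >= 0")
  }
  if (cfg$baseline_freq <= 0) stop_invalid("baseline_freq must be positive")
  invisible(cfg)
}

# 1/f^beta shaped Gaussian background. The unmodulated background is scaled
# to `target_rms`; in the flapping state its power is multiplied by `boost`
# below `boost_hi` and by `suppress` above `suppress_lo` (the flapping-state
# spectral redistribution: low band up, high band down).
shaped_background <- function(n, fs, beta, target_rms, boost = 1,
                              boost_hi = 15, suppress = 1, suppress_lo = 30) {
  w <- stats::rnorm(n)
  if (target_rms == 0) return(numeric(n))
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n           # |frequency| of each DFT bin
  H <- ifelse(f > 0, f^(-beta / 2), 0)   # DC bin zeroed
  base <- Re(stats::fft(W * H, inverse = TRUE)) / n
  scale <- target_rms / rms(base)
  if (boost == 1 && suppress == 1) return(base * scale)
  H[f > 0 & f <= boost_hi] <- H[f > 0 & f <= boost_hi] * sqrt(boost)
  H[f >= suppress_lo] <- H[f >= suppress_lo] * sqrt(suppress)
  (Re(stats::fft(W * H, inverse = TRUE)) / n) * scale
}

#' Generate a synthetic optic-lobe LFP trace
#'
#' Simulates a single-channel LFP trace in either the flapping or the calm
#' behavioral state. Both states share the DC offset, 0.7 Hz-centered
#' baseline wander and 1/f background; the flapping state additionally
#' carries a narrow-band oscillation inside `flap_band` (instantaneous
#' frequency performs a reflected random walk within the band) and a
#' redistribution of background power toward the 0--`lowband_hi` Hz band.
#'
#' With the same configuration and state the output is bit-identical across
#' calls; the caller's RNG state is left untouched.
#'
#' @param config An [lfp_gen_config()].
#' @param state `"flapping"` or `"calm"`.
#'
#' @return An [lfp_trace()] of `round(sampling_rate * duration_s)` samples,
#'   labeled with `state`; `meta` echoes the config and seed.
#' @export
#' @examples
#' tr <- generate_lfp(lfp_gen_config(duration_s = 2, seed = 42), "flapping")
#' tr
generate_lfp <- function(config, state = c("flapping", "calm")) {
  if (!inherits(config, "lfp_gen_config")) config <- do.call(lfp_gen_config, config)
  validate_lfp_gen_config(config)
  state <- match.arg(state)
  fs <- config$sampling_rate
  n <- round(fs * config$duration_s)
  if (n < 2L) stop_invalid("config yields fewer than 2 samples")

  x <- with_seed(config$seed, {
    flapping <- state == "flapping"
    bg <- if (config$background_amp > 0) {
      shaped_background(n, fs, config$background_exponent,
                        config$background_amp,
                        boost = if (flapping) config$lowband_boost else 1,
                        boost_hi = config$lowband_hi,
                        suppress = if (flapping) config$highband_suppress else 1,
                        suppress_lo = config$flap_band[2])
    } else numeric(n)

    bl <- numeric(n)
    if (config$baseline_amp > 0) {
      t <- (0:(n - 1)) / fs
      phase <- stats::runif(1, 0, 2 * pi)
      bl <- config$baseline_amp * sin(2 * pi * config$baseline_freq * t + phase)
      rw <- cumsum(stats::rnorm(n))
      rw <- rw - mean(rw)
      if (rms(rw) > 0) bl <- bl + rw * (0.2 * config$baseline_amp / rms(rw))
    }

    osc <- numeric(n)
    if (flapping && config$flap_osc_amp > 0) {
      lo <- config$flap_band[1]; hi <- config$flap_band[2]
      # center frequency clear of the band edges so the spectral peak stays
      # inside the band after estimation smearing
      margin <- 0.15 * (hi - lo)
      f0 <- stats::runif(1, lo + margin, hi - margin)
      # instantaneous frequency: slow random walk reflected into the band
      fi <- reflect_into(f0 + cumsum(stats::rnorm(n, 0, 0.005)), lo, hi)
      ph0 <- stats::runif(1, 0, 2 * pi)
      osc <- config$flap_osc_amp * sin(ph0 + 2 * pi * cumsum(fi) / fs)
    }

    config$dc_offset + bg + bl + osc
  })

  lfp_trace(x, fs, state = state,
            meta = list(seed = config$seed, generator = "generate_lfp",
                        config = unclass(config)))
}
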