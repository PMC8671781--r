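#' Integrated power of a PSD over a frequency band
#'
#' Trapezoidal integral of the spectrum over `[lo, hi]`, with linear
#' interpolation at band edges that fall between grid points. Additive over
#' adjacent bands split at a grid point.
#'
#' @param psd A [ar_psd()] result (`psd_estimate`) or an [average_psd()]
#'   result (`avg_psd`, integrated over its mean power).
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <=` Nyquist.
#' @return Band power in uV^2.
#' @export
band_power <- function(psd, lo, hi) {
  fp <- psd_curve(psd)
  f <- fp$frequencies
  p <- fp$power
  if (!(lo >= f[1] && hi <= f[length(f)] && lo < hi)) {
    stop_invalid("band [", lo, ", ", hi, "] Hz lies outside the PSD grid ",
                 "[", f[1], ", ", f[length(f)], "] Hz")
  }
  inner <- which(f > lo & f < hi)
  fk <- c(lo, f[inner], hi)
  pk <- c(stats::approx(f, p, xout = lo)$y, p[inner],
          stats::approx(f, p, xout = hi)$y)
  sum(diff(fk) * (pk[-1] + pk[-length(pk)]) / 2)
}

psd_curve <- function(psd) {
  if (inherits(psd, "psd_estimate")) {
    list(frequencies = psd$frequencies, power = psd$power)
  } else if (inherits(psd, "avg_psd")) {
    list(frequencies = psd$frequencies, power = psd$mean_power)
  } else {
    stop_invalid("expected a psd_estimate or avg_psd object")
  }
}

# Indices of strict local maxima of p; plateaus collapse to their first
# index (ties broken toward lower frequency).
strict_local_maxima <- function(p) {
  find_extrema(p)$maxima
}

#' Detect the flapping-band spectral peak
#'
#' Finds the highest strict local maximum of the spectrum whose frequency
#' lies inside `band` (default 20--30 Hz, where flapping-state optic-lobe
#' spectra carry a characteristic peak). Prominence is the peak power
#' divided by the median in-band power. Plateaus are broken toward lower
#' frequency.
#'
#' @param psd A `psd_estimate` or `avg_psd`.
#' @param band Length-2 numeric band (Hz).
#' @return A list with `freq` (Hz) and `prominence` (>= 1), or `NULL` if no
#'   strict local maximum lies in the band.
#' @export
detect_flapband_peak <- function(psd, band = c(20, 30)) {
  fp <- psd_curve(psd)
  f <- fp$frequencies
  p <- fp$power
  if (!(band[1] >= f[1] && band[2] <= f[length(f)] && band[1] < band[2])) {
    stop_invalid("band must lie within the PSD grid")
  }
  in_band <- which(f >= band[1] & f <= band[2])
  peaks <- strict_local_maxima(p)
  peaks <- peaks[peaks %in% in_band]
  if (length(peaks) == 0L) return(NULL)
  best <- peaks[which.max(p[peaks])]
  med <- stats::median(p[in_band])
  list(freq = f[best],
       prominence = if (med > 0) p[best] / med else Inf)
}

#' Spectral features of one PSD
#'
#' Computes the features used to discriminate the flapping from the calm
#' state: integrated 0--15 Hz power, the flapping-band peak (frequency and
#' prominence, if any), and a fluctuation score defined as the number of
#' strict local maxima of log-power below `fluct_max_freq`.
#'
#' @param psd A `psd_estimate` or `avg_psd`.
#' @param flap_band Flapping peak search band (Hz), default 20--30.
#' @param lowband Low band for integrated power (Hz), default 0--15.
#' @param fluct_max_freq Upper frequency for the fluctuation count (Hz).
#' @return An object of class `spectral_features`: list with
#'   `lowband_power`, `flapband_peak_freq` (or `NA`),
#'   `flapband_peak_prominence` (or `NA`), `fluctuation_score`,
#'   `state_call` (`NA` until [classify_state()] is applied), `state_truth`
#'   (the generator label carried by the PSD, if any).
#' @export
spectral_features <- function(psd, flap_band = c(20, 30), lowband = c(0, 15),
                              fluct_max_freq = 50) {
  fp <- psd_curve(psd)
  peak <- detect_flapband_peak(psd, flap_band)
  sel <- fp$frequencies < fluct_max_freq
  logp <- log(pmax(fp$power[sel], .Machine$double.xmin))
  structure(
    list(lowband_power = band_power(psd, lowband[1], lowband[2]),
         flapband_peak_freq = if (is.null(peak)) NA_real_ else peak$freq,
         flapband_peak_prominence = if (is.null(peak)) NA_real_ else peak$prominence,
         fluctuation_score = length(strict_local_maxima(logp)),
         state_call = NA_character_,
         state_truth = if (!is.null(psd$state)) psd$state else "unknown"),
    class = "spectral_features"
  )
}

#' @export
print.spectral_features <- function(x, ...) {
  cat("<spectral_features>\n")
  cat(sprintf("  lowband (0-15 Hz) power: %.4g uV^2\n", x$lowband_power))
  if (is.na(x$flapband_peak_freq)) {
    cat("  flap-band peak: absent\n")
  } else {
    cat(sprintf("  flap-band peak: %.2f Hz, prominence %.2f\n",
                x$flapband_peak_freq, x$flapband_peak_prominence))
  }
  cat(sprintf("  fluctuation score: %d; state call: %s\n",
              x$fluctuation_score, x$state_call))
  invisible(x)
}

#' Default flapping/calm decision thresholds
#'
#' @param prominence Minimum flap-band peak prominence (ratio).
#' @param fluctuation Minimum fluctuation score (count).
#' @param lowband_ratio Minimum ratio of low-band power to a calm reference.
#' @return A named list of thresholds.
#' @export
state_thresholds <- function(prominence = 1.5, fluctuation = 3,
                             lowband_ratio = 1.3) {
  list(prominence = prominence, fluctuation = fluctuation,
       lowband_ratio = lowband_ratio)
}

#' Classify a PSD's behavioral state from its spectral features
#'
#' Deterministic rule operationalizing the three qualitative spectral cues
#' of the flapping state: the trace is called `"flapping"` iff a flap-band
#' peak exists with prominence at least `thresholds$prominence` AND (the
#' fluctuation score is at least `thresholds$fluctuation` OR, when a calm
#' low-band reference is supplied, the low-band power ratio against it is at
#' least `thresholds$lowband_ratio`). Otherwise the call is `"calm"`.
#'
#' The applied rule and thresholds are recorded in the returned object
#' (`decision` element) and echoed via [message()] when
#' `options(beelfp.verbose = TRUE)`.
#'
#' @param features A [spectral_features()] object.
#' @param thresholds A [state_thresholds()] list.
#' @param calm_lowband Low-band power of a calm reference spectrum (uV^2),
#'   or `NULL` to disable the ratio clause.
#' @param use_lowband_ratio Whether the ratio clause participates in the
#'   disjunction; defaults to `TRUE` when `calm_lowband` is supplied.
#'   Enabling it without a reference is a configuration error.
#' @return The `features` object with `state_call` set and a `decision`
#'   record (rule string, thresholds, clause outcomes) attached.
#' @export
classify_state <- function(features, thresholds = state_thresholds(),
                           calm_lowband = NULL,
                           use_lowband_ratio = !is.null(calm_lowband)) {
  stopifnot(inherits(features, "spectral_features"))
  if (use_lowband_ratio && is.null(calm_lowband)) {
    stop_invalid("the low-band ratio clause is enabled but no calm ",
                 "reference (calm_lowband) was supplied")
  }
  peak_ok <- !is.na(features$flapband_peak_prominence) &&
    features$flapband_peak_prominence >= thresholds$prominence
  fluct_ok <- features$fluctuation_score >= thresholds$fluctuation
  ratio <- if (use_lowband_ratio) features$lowband_power / calm_lowband else NA_real_
  ratio_ok <- use_lowband_ratio && is.finite(ratio) &&
    ratio >= thresholds$lowband_ratio
  call <- if (peak_ok && (fluct_ok || ratio_ok)) "flapping" else "calm"

  features$state_call <- call
  features$decision <- list(
    rule = "flapping iff (peak prominence >= t_p) AND (fluctuation >= t_f OR lowband ratio >= t_r)",
    thresholds = thresholds, peak_ok = peak_ok, fluct_ok = fluct_ok,
    lowband_ratio = ratio, ratio_ok = ratio_ok)
  vlog("classify", sprintf(
    "peak_ok=%s fluct_ok=%s ratio=%.3g ratio_ok=%s -> %s (t_p=%g t_f=%g t_r=%g)",
    peak_ok, fluct_ok, ratio, ratio_ok, call, thresholds$prominence,
    thresholds$fluctuation, thresholds$lowband_ratio))
  features
}

#' Transition frequency between flapping and calm average spectra
#'
#' Returns the lowest frequency at which the difference
#' `flap$mean_power - calm$mean_power` changes sign from positive to
#' negative, located by linear interpolation between the bracketing bins
#' (exact zeros between a positive and a negative bin are taken as the
#' crossing point). Below this frequency the flapping state carries more
#' power than the calm state; above it, less.
#'
#' @param flap,calm [average_psd()] results on a shared frequency grid.
#' @return Crossing frequency in Hz, or `NULL` if the difference never
#'   crosses from positive to negative.
#' @export
find_transition_frequency <- function(flap, calm) {
  stopifnot(inherits(flap, "avg_psd"), inherits(calm, "avg_psd"))
  if (!isTRUE(all.equal(flap$frequencies, calm$frequencies))) {
    stop_invalid("flap and calm average spectra must share one grid")
  }
  f <- flap$frequencies
  d <- flap$mean_power - calm$mean_power
  i <- 1L
  n <- length(d)
  while (i < n) {
    if (d[i] > 0) {
      j <- i + 1L
      while (j <= n && d[j] == 0) j <- j + 1L
      if (j <= n && d[j] < 0) {
        if (j > i + 1L) return(f[i + 1L])  # crossing through exact zeros
        return(f[i] + d[i] * (f[j] - f[i]) / (d[i] - d[j]))
      }
    }
    i <- i + 1L
  }
  NULL
}
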