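#' Burg autoregressive model fit
#'
#' Fits an AR(p) model to a trace by the Burg lattice recursion, which
#' minimizes the summed forward and backward prediction-error power at each
#' stage. The coefficient convention is
#' `x_t + a_1 x_{t-1} + ... + a_p x_{t-p} = e_t`, i.e. the returned
#' `coefficients` are the polynomial coefficients of `A(z)`; note this is
#' the negative of the convention used by [stats::ar.burg()].
#'
#' At stage m the reflection coefficient is
#' `k_m = -2 sum f_{m-1}(t) b_{m-1}(t-1) / sum (f_{m-1}(t)^2 + b_{m-1}(t-1)^2)`,
#' coefficients are updated by the Levinson step and the prediction errors by
#' the lattice step. All reflection coefficients satisfy `|k| <= 1`, so the
#' fitted model is stable. The final prediction-error power is returned as
#' `noise_variance`.
#'
#' The trace is expected to be DC-free ([remove_dc()]); a warning is raised
#' if |mean| exceeds 1e-6 of the RMS. A zero signal yields all-zero
#' coefficients and zero variance.
#'
#' @param trace An [lfp_trace()] (or numeric vector, in which case
#'   `sampling_rate` must be supplied).
#' @param order AR order p >= 1; must be less than the trace length.
#'   Default 15.
#' @param sampling_rate Sampling rate in Hz when `trace` is a bare vector.
#'
#' @return An object of class `ar_model`: list with `order`, `coefficients`
#'   (a_1..a_p), `reflection` (k_1..k_p), `noise_variance`, `sampling_rate`,
#'   `n`, `state`, `meta`.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 2048))
#' fit <- burg_ar(lfp_trace(x, 1000), order = 1)
#' fit$coefficients  # close to -0.5
burg_ar <- function(trace, order = 15, sampling_rate = NULL) {
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
    state <- trace$state
    meta <- trace$meta
  } else {
    x <- as.numeric(trace)
    if (is.null(sampling_rate)) {
      stop_invalid("sampling_rate is required when trace is a bare vector")
    }
    fs <- sampling_rate
    state <- "unknown"
    meta <- list()
  }
  n <- length(x)
  if (order < 1L) stop_invalid("order must be >= 1")
  if (order >= n) stop_invalid("order must be less than the trace length")
  if (rms(x) > 0 && abs(mean(x)) > 1e-6 * rms(x)) {
    warning("burg_ar: trace does not look DC-free (|mean| > 1e-6 * RMS); ",
            "consider remove_dc() first", call. = FALSE)
  }

  f <- x
  b <- x
  a <- numeric(0)
  k_all <- numeric(order)
  E <- mean(x^2)
  for (m in seq_len(order)) {
    ff <- f[(m + 1):n]
    bb <- b[m:(n - 1)]
    den <- sum(ff^2) + sum(bb^2)
    k <- if (den > 0) -2 * sum(ff * bb) / den else 0
    k_all[m] <- k
    a <- c(a + k * rev(a), k)
    f_new <- ff + k * bb
    b_new <- bb + k * ff
    f[(m + 1):n] <- f_new
    b[(m + 1):n] <- b_new
    E <- E * (1 - k^2)
  }

  structure(
    list(order = order, coefficients = a, reflection = k_all,
         noise_variance = max(E, 0), sampling_rate = fs, n = n,
         state = state, meta = meta),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> Burg AR(%d), n = %d, fs = %g Hz\n",
              x$order, x$n, x$sampling_rate))
  cat(sprintf("  noise variance: %.6g uV^2; max |reflection|: %.4f\n",
              x$noise_variance, max(abs(x$reflection))))
  invisible(x)
}

#' AR power spectral density on a DFT grid
#'
#' Evaluates the one-sided PSD of a fitted AR model,
#' `P(f) = (sigma^2 / fs) / |1 + sum_k a_k exp(-i 2 pi f k / fs)|^2`,
#' on the grid `f_j = j * fs / nfft`, `j = 0..nfft/2` (`nfft/2 + 1` points
#' spanning 0 to the Nyquist frequency). The one-sided convention doubles
#' the interior bins (not the DC and Nyquist bins), so the trapezoidal
#' integral of the spectrum over `[0, fs/2]` approximates the process
#' variance.
#'
#' @param model An [burg_ar()] result, or any `ar_model`-shaped list. A
#'   model whose recorded reflection coefficients exceed 1 in magnitude is
#'   refused (its spectrum would come from an unstable filter).
#' @param nfft Number of DFT points (default 1024). Must be at least twice
#'   the model order; a warning is raised if not a power of two.
#'
#' @return An object of class `psd_estimate`: list with `frequencies` (Hz),
#'   `power` (uV^2/Hz), `nfft`, `sampling_rate`, `state`, `meta`.
#' @export
ar_psd <- function(model, nfft = 1024) {
  stopifnot(inherits(model, "ar_model"))
  p <- model$order
  if (nfft < 2 * p) stop_invalid("nfft must be at least 2 * order")
  if (bitwAnd(nfft, nfft - 1L) != 0L) {
    warning("ar_psd: nfft = ", nfft, " is not a power of two", call. = FALSE)
  }
  if (length(model$reflection) && any(abs(model$reflection) > 1)) {
    stop_invalid("refusing to evaluate the spectrum of an unstable AR model ",
                 "(|reflection coefficient| > 1)")
  }
  fs <- model$sampling_rate
  nh <- nfft %/% 2
  A <- stats::fft(c(1, model$coefficients, rep(0, nfft - p - 1)))[1:(nh + 1)]
  pwr <- (model$noise_variance / fs) / Mod(A)^2
  if (nh > 1L) pwr[2:nh] <- 2 * pwr[2:nh]  # one-sided doubling, interior bins
  structure(
    list(frequencies = (0:nh) * fs / nfft, power = pwr, nfft = nfft,
         sampling_rate = fs, state = model$state, meta = model$meta),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%g Hz, nfft = %d, state = %s\n",
              length(x$frequencies), max(x$frequencies), x$nfft, x$state))
  invisible(x)
}

#' Average several PSD estimates on a shared grid
#'
#' Pointwise arithmetic mean of the input spectra, with a per-frequency
#' error given either as the sample standard deviation (n-1 denominator) or
#' the standard error of the mean.
#'
#' @param estimates List of [ar_psd()] results on identical frequency grids.
#' @param error_kind `"SD"` (default) or `"SEM"`.
#'
#' @return An object of class `avg_psd`: list with `frequencies`,
#'   `mean_power`, `error`, `n_samples`, `error_kind`, `sampling_rate`,
#'   `state`.
#' @export
average_psd <- function(estimates, error_kind = c("SD", "SEM")) {
  error_kind <- match.arg(error_kind)
  if (length(estimates) < 1L) stop_invalid("average_psd needs >= 1 estimate")
  stopifnot(all(vapply(estimates, inherits, logical(1), "psd_estimate")))
  f <- estimates[[1]]$frequencies
  for (e in estimates[-1]) {
    if (!isTRUE(all.equal(e$frequencies, f))) {
      stop_invalid("all PSD estimates must share one frequency grid")
    }
  }
  P <- vapply(estimates, `[[`, numeric(length(f)), "power")
  P <- matrix(P, nrow = length(f))
  n <- length(estimates)
  m <- rowMeans(P)
  err <- if (n == 1L) rep(0, length(f)) else apply(P, 1L, stats::sd)
  if (error_kind == "SEM") err <- err / sqrt(n)
  states <- unique(vapply(estimates, `[[`, character(1), "state"))
  structure(
    list(frequencies = f, mean_power = m, error = err, n_samples = n,
         error_kind = error_kind,
         sampling_rate = estimates[[1]]$sampling_rate,
         state = if (length(states) == 1L) states else "unknown"),
    class = "avg_psd"
  )
}

#' @export
print.avg_psd <- function(x, ...) {
  cat(sprintf("<avg_psd> mean of %d spectra (%s error), 0-%g Hz, state = %s\n",
              x$n_samples, x$error_kind, max(x$frequencies), x$state))
  invisible(x)
}
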