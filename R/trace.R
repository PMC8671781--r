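#' Construct an LFP signal trace
#'
#' A uniformly sampled single-channel voltage series. This is the common
#' container consumed by the preprocessing and spectral stages.
#'
#' @param samples Numeric vector of voltages (microvolts), one per sample.
#' @param sampling_rate Sampling rate in Hz.
#' @param state Behavioral state label: `"flapping"`, `"calm"` or `"unknown"`.
#' @param meta Free-form provenance list (seed, source file, config echo).
#'
#' @return An object of class `lfp_trace`: a list with elements `samples`,
#'   `sampling_rate`, `state`, `meta`.
#' @export
#' @examples
#' tr <- lfp_trace(sin(2 * pi * 25 * seq(0, 1, by = 1e-3)), 1000)
#' tr
lfp_trace <- function(samples, sampling_rate, state = "unknown", meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop_invalid("an LFP trace needs at least 2 samples")
  }
  if (!all(is.finite(samples))) {
    stop_invalid("LFP trace samples must all be finite")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_invalid("sampling_rate must be a single positive number (Hz)")
  }
  state <- match.arg(state, c("flapping", "calm", "unknown"))
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         state = state, meta = meta),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.3f s), state = %s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$state))
  cat(sprintf("  amplitude: mean %.3f, sd %.3f uV\n",
              mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}

#' @export
length.lfp_trace <- function(x) length(x$samples)
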