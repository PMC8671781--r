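# Delimited-text formats: comma-separated, UTF-8, header row; missing
# values written as empty fields. Signal files carry a JSON sidecar
# (<path>.json) with the sampling rate, state label, seed and config echo.

#' Write an LFP trace to delimited text with a JSON sidecar
#'
#' The trace is written as a two-column CSV (`time_s`, `amplitude_uv`) and a
#' sidecar `<path>.json` holding `sampling_rate`, `state`, `seed` and the
#' generator config echo, so a file round-trips to the same object.
#'
#' @param trace An [lfp_trace()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_signal <- function(trace, path) {
  stopifnot(inherits(trace, "lfp_trace"))
  n <- length(trace$samples)
  df <- data.frame(time_s = (0:(n - 1)) / trace$sampling_rate,
                   amplitude_uv = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(sampling_rate = trace$sampling_rate, state = trace$state,
               seed = trace$meta$seed, config = trace$meta$config)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read an LFP trace written by [write_signal()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist (it carries
#'   the sampling rate).
#' @return An [lfp_trace()].
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop_invalid("signal file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop_invalid("missing sidecar ", sp, " (holds the sampling rate)")
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_uv") %in% names(df))) {
    stop_invalid("signal file ", path,
                 " must have columns time_s, amplitude_uv")
  }
  bad <- which(!is.finite(df$amplitude_uv))
  if (length(bad)) {
    stop_invalid("non-finite amplitude in ", path, " at line ",
                 bad[1] + 1L)  # +1 for the header row
  }
  lfp_trace(df$amplitude_uv, side$sampling_rate,
            state = if (is.null(side$state)) "unknown" else side$state,
            meta = list(seed = side$seed, source = path,
                        config = side$config))
}

#' Write a stimulation-trial table to delimited text
#'
#' Comma-separated with a header row; absent responses of non-initiated
#' trials are empty fields.
#'
#' @param trials Trial `data.frame` (see [generate_behavior_trials()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a stimulation-trial table written by [write_trials()]
#'
#' Validates the invariant that non-initiated trials carry no responses;
#' violations are reported with their line number. A header-only file reads
#' as an empty (zero-row) table.
#'
#' @param path CSV path.
#' @return A trial `data.frame`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_invalid("trial file not found: ", path)
  df <- utils::read.csv(path, na.strings = "")
  need <- c("stim_freq_hz", "stim_voltage_v", "initiated",
            "flap_freq_hz", "flap_dur_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_invalid("trial file ", path, " is missing columns: ",
                 paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    df$initiated <- logical(0)
    df$flap_freq_hz <- numeric(0)
    df$flap_dur_ms <- numeric(0)
    return(df)
  }
  if (is.character(df$initiated)) {
    df$initiated <- toupper(df$initiated) %in% c("TRUE", "T", "1")
  }
  df$initiated <- as.logical(df$initiated)
  df$flap_freq_hz <- as.numeric(df$flap_freq_hz)
  df$flap_dur_ms <- as.numeric(df$flap_dur_ms)
  bad <- which(!df$initiated &
                 (!is.na(df$flap_freq_hz) | !is.na(df$flap_dur_ms)))
  if (length(bad)) {
    stop_invalid("trial file ", path, ", line ", bad[1] + 1L,
                 ": non-initiated trial carries a response")
  }
  df
}

#' Write an EMD decomposition as a multi-column table
#'
#' Columns `imf_1` .. `imf_k`, `residue`.
#'
#' @param decomp An [emd()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_imfs <- function(decomp, path) {
  stopifnot(inherits(decomp, "imf_set"))
  cols <- decomp$imfs
  names(cols) <- if (length(cols)) paste0("imf_", seq_along(cols)) else character(0)
  cols$residue <- decomp$residue
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Write a PSD or average PSD as a delimited table
#'
#' Columns `frequency_hz`, `power` and, for averages, `error`.
#'
#' @param psd A `psd_estimate` or `avg_psd`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  if (inherits(psd, "avg_psd")) {
    df <- data.frame(frequency_hz = psd$frequencies, power = psd$mean_power,
                     error = psd$error)
  } else {
    fp <- psd_curve(psd)
    df <- data.frame(frequency_hz = fp$frequencies, power = fp$power)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
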