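#' Flight-initiation success-rate grid
#'
#' Groups stimulation trials by exact (stimulus frequency, voltage) pair and
#' computes per-cell success rate `P = #initiated / #trials` — the fraction
#' of trials in each cell that evoked flight initiation. Cells of the full
#' frequency-by-voltage cross grid with no trials are `NA`.
#'
#' @param trials A trial `data.frame` as produced by
#'   [generate_behavior_trials()] or [read_trials()] (columns
#'   `stim_freq_hz`, `stim_voltage_v`, `initiated`).
#' @return An object of class `success_rate_table`: list with `frequencies`
#'   (row values, Hz), `voltages` (column values, V), `p` (rate matrix),
#'   `n_trials` and `n_initiated` (count matrices).
#' @export
#' @examples
#' tr <- generate_behavior_trials(behavior_gen_config(trials_per_cell = 20))
#' success_rate_table(tr)
success_rate_table <- function(trials) {
  check_trials(trials)
  if (nrow(trials) < 1L) stop_invalid("success_rate_table needs >= 1 trial")
  fr <- sort(unique(trials$stim_freq_hz))
  vo <- sort(unique(trials$stim_voltage_v))
  fi <- factor(trials$stim_freq_hz, levels = fr)
  vi <- factor(trials$stim_voltage_v, levels = vo)
  n_tab <- table(fi, vi)
  s_tab <- table(fi[trials$initiated], vi[trials$initiated])
  n <- matrix(as.integer(n_tab), nrow = length(fr),
              dimnames = list(frequency_hz = fr, voltage_v = vo))
  s <- matrix(as.integer(s_tab), nrow = length(fr),
              dimnames = dimnames(n))
  p <- ifelse(n > 0, s / n, NA_real_)
  structure(
    list(frequencies = fr, voltages = vo, p = p, n_trials = n,
         n_initiated = s),
    class = "success_rate_table"
  )
}

#' @export
print.success_rate_table <- function(x, digits = 2, ...) {
  cat(sprintf("<success_rate_table> %d frequencies x %d voltages, %d trials\n",
              length(x$frequencies), length(x$voltages), sum(x$n_trials)))
  print(round(x$p, digits))
  invisible(x)
}

#' Narrow the stimulation grid to the high-success region
#'
#' Returns the minimal contiguous frequency range and voltage range whose
#' cells cover every grid cell with success rate at least `criterion`
#' (default 0.8, the screening criterion used to narrow the stimulus
#' search). The ranges bound the qualifying set; cells inside the ranges may
#' individually fall below the criterion.
#'
#' @param table A [success_rate_table()].
#' @param criterion Success-rate threshold in \[0, 1\].
#' @return A list with `freq_range` and `voltage_range` (each `c(lo, hi)` in
#'   the grid's units) and `n_qualifying`, or `NULL` if no cell qualifies.
#' @export
refine_grid <- function(table, criterion = 0.8) {
  stopifnot(inherits(table, "success_rate_table"))
  ok <- which(!is.na(table$p) & table$p >= criterion, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(NULL)
  list(freq_range = range(table$frequencies[ok[, 1]]),
       voltage_range = range(table$voltages[ok[, 2]]),
       n_qualifying = nrow(ok))
}

#' Summarize flapping responses of successful trials
#'
#' Over the initiated trials with both responses recorded, computes the
#' sample mean and SD (n-1 denominator) of flapping duration (ms) and
#' flapping frequency (Hz), their Pearson correlation, and their sample
#' covariance (n-1 denominator). Non-initiated trials are excluded.
#'
#' @param trials A trial `data.frame` (columns `initiated`, `flap_freq_hz`,
#'   `flap_dur_ms`).
#' @return An object of class `behavior_summary`: list with `n`, `dur_mean`,
#'   `dur_sd`, `freq_mean`, `freq_sd`, `pearson_r`, `covariance`.
#' @export
summarize_flight <- function(trials) {
  check_trials(trials)
  ok <- trials$initiated & !is.na(trials$flap_freq_hz) &
    !is.na(trials$flap_dur_ms)
  d <- trials$flap_dur_ms[ok]
  f <- trials$flap_freq_hz[ok]
  if (length(d) < 2L) {
    stop_invalid("summarize_flight needs at least 2 initiated trials with ",
                 "complete responses")
  }
  structure(
    list(n = length(d),
         dur_mean = mean(d), dur_sd = stats::sd(d),
         freq_mean = mean(f), freq_sd = stats::sd(f),
         pearson_r = stats::cor(d, f),
         covariance = stats::cov(d, f)),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> n = %d successful trials\n", x$n))
  cat(sprintf("  flapping duration:  mean %.3f ms, SD %.3f ms\n",
              x$dur_mean, x$dur_sd))
  cat(sprintf("  flapping frequency: mean %.3f Hz, SD %.3f Hz\n",
              x$freq_mean, x$freq_sd))
  cat(sprintf("  Pearson r = %.4f, covariance = %.2f ms*Hz\n",
              x$pearson_r, x$covariance))
  invisible(x)
}

check_trials <- function(trials) {
  if (!is.data.frame(trials)) stop_invalid("trials must be a data.frame")
  need <- c("stim_freq_hz", "stim_voltage_v", "initiated",
            "flap_freq_hz", "flap_dur_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop_invalid("trial table is missing columns: ",
                 paste(miss, collapse = ", "))
  }
  bad <- which(!trials$initiated &
                 (!is.na(trials$flap_freq_hz) | !is.na(trials$flap_dur_ms)))
  if (length(bad)) {
    stop_invalid("non-initiated trials must have empty responses ",
                 "(first offending row: ", bad[1], ")")
  }
  invisible(trials)
}
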