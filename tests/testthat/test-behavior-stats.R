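mk_trials <- function(f, u, init, freq = NULL, dur = NULL) {
  n <- length(f)
  data.frame(stim_freq_hz = f, stim_voltage_v = u, duty_ratio = 0.4,
             polarity = "bipolar", stim_duration_s = 1, initiated = init,
             flap_freq_hz = if (is.null(freq)) ifelse(init, 100, NA_real_) else freq,
             flap_dur_ms = if (is.null(dur)) ifelse(init, 400, NA_real_) else dur)
}

test_that("success_rate_table computes per-cell ratios and counts", {
  tr <- mk_trials(rep(60, 8), rep(7, 8), c(rep(TRUE, 4), rep(FALSE, 4)))
  tab <- success_rate_table(tr)
  expect_equal(tab$p[1, 1], 0.5)
  expect_equal(sum(tab$n_trials), 8L)

  # all initiated -> every populated cell P = 1
  tr2 <- mk_trials(c(20, 20, 60), c(3, 7, 7), rep(TRUE, 3))
  tab2 <- success_rate_table(tr2)
  expect_true(all(tab2$p[!is.na(tab2$p)] == 1))
  # absent cells are NA and counts sum to the trial count
  expect_true(any(is.na(tab2$p)))
  expect_equal(sum(tab2$n_trials), 3L)
  expect_error(success_rate_table(tr[0, ]), "1 trial")
})

test_that("the empirical success surface peaks near the optimal stimulus", {
  trials <- generate_behavior_trials(
    behavior_gen_config(trials_per_cell = 300, seed = 6))
  tab <- success_rate_table(trials)
  best <- which(tab$p == max(tab$p, na.rm = TRUE), arr.ind = TRUE)[1, ]
  # within one grid step of (60 Hz, 7 V)
  expect_lte(abs(which(tab$frequencies == 60) - best[1]), 1L)
  expect_lte(abs(which(tab$voltages == 7) - best[2]), 1L)
})

test_that("refine_grid returns minimal bounding ranges of qualifying cells", {
  # constructed block: rows 3..5, cols 5..6 qualify
  tr <- NULL
  freqs <- c(1, 20, 40, 60, 80, 100)
  volts <- 3:8
  for (i in seq_along(freqs)) for (j in seq_along(volts)) {
    good <- i >= 3 && i <= 5 && j >= 5 && j <= 6
    tr <- rbind(tr, mk_trials(rep(freqs[i], 4), rep(volts[j], 4),
                              rep(good, 4)))
  }
  rg <- refine_grid(success_rate_table(tr))
  expect_equal(rg$freq_range, c(40, 80))
  expect_equal(rg$voltage_range, c(7, 8))

  # no qualifying cell
  none <- success_rate_table(mk_trials(rep(60, 4), rep(7, 4), rep(FALSE, 4)))
  expect_null(refine_grid(none))
  # single qualifying cell: degenerate ranges
  one <- success_rate_table(mk_trials(rep(60, 4), rep(7, 4), rep(TRUE, 4)))
  expect_equal(refine_grid(one)$freq_range, c(60, 60))
})

test_that("refine_grid ranges contain every qualifying cell on random tables", {
  for (sd in 1:20) {
    set.seed(sd)
    nf <- sample(3:6, 1)
    nv <- sample(3:6, 1)
    tr <- NULL
    for (f in seq_len(nf) * 10) for (u in seq_len(nv)) {
      k <- 5
      init <- runif(k) < runif(1)
      tr <- rbind(tr, mk_trials(rep(f, k), rep(u, k), init))
    }
    tab <- success_rate_table(tr)
    rg <- refine_grid(tab, criterion = 0.8)
    q <- which(!is.na(tab$p) & tab$p >= 0.8, arr.ind = TRUE)
    if (is.null(rg)) {
      expect_equal(nrow(q), 0L)
    } else {
      expect_true(all(tab$frequencies[q[, 1]] >= rg$freq_range[1] &
                        tab$frequencies[q[, 1]] <= rg$freq_range[2]))
      expect_true(all(tab$voltages[q[, 2]] >= rg$voltage_range[1] &
                        tab$voltages[q[, 2]] <= rg$voltage_range[2]))
    }
  }
})

test_that("summarize_flight reproduces hand-computed statistics", {
  tr <- mk_trials(rep(60, 3), rep(7, 3), rep(TRUE, 3),
                  freq = c(100, 120, 140), dur = c(1, 2, 3))
  s <- summarize_flight(tr)
  expect_equal(s$n, 3L)
  expect_equal(s$freq_mean, 120)
  expect_equal(s$freq_sd, 20)
  # perfect anticorrelation
  tr2 <- mk_trials(rep(60, 3), rep(7, 3), rep(TRUE, 3),
                   freq = c(-1, -2, -3), dur = c(1, 2, 3))
  expect_equal(summarize_flight(tr2)$pearson_r, -1)
  # non-initiated trials are excluded
  tr3 <- rbind(tr, mk_trials(rep(3, 5), rep(3, 5), rep(FALSE, 5)))
  expect_equal(summarize_flight(tr3)$n, 3L)
  expect_error(summarize_flight(mk_trials(60, 7, TRUE)), "at least 2")
})

test_that("pearson_r matches a brute-force evaluation on random fixtures", {
  for (sd in 1:10) {
    set.seed(sd)
    n <- sample(5:50, 1)
    freq <- rnorm(n, 120, 20)
    dur <- rlnorm(n, 6, 0.5)
    tr <- mk_trials(rep(60, n), rep(7, n), rep(TRUE, n), freq = freq, dur = dur)
    s <- summarize_flight(tr)
    expect_equal(s$pearson_r, pearson_brute(dur, freq), tolerance = 1e-12)
    expect_equal(s$covariance, sum((dur - mean(dur)) * (freq - mean(freq))) / (n - 1),
                 tolerance = 1e-12)
  }
})

test_that("trial tables violating the response invariant are rejected", {
  bad <- mk_trials(rep(60, 2), rep(7, 2), c(TRUE, FALSE))
  bad$flap_freq_hz[2] <- 99
  expect_error(success_rate_table(bad), "row: 2")
})
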