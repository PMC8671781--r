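#' Configuration for the synthetic stimulation-trial generator
#'
#' Describes the behavioral experiment: a grid of stimulus frequencies and
#' voltage amplitudes, a unimodal flight-initiation probability surface
#' peaking at (`f_opt`, `u_opt`), and the joint distribution of the flapping
#' responses on successful trials.
#'
#' The initiation probability is a separable product of Gaussian bumps in
#' log-frequency and log-voltage:
#' `p(F, U) = peak_prob * exp(-(log(F/f_opt))^2 / (2 f_width^2)
#'                            -(log(U/u_opt))^2 / (2 u_width^2))`.
#'
#' Flapping duration is lognormal with the configured mean/SD (its SD is
#' comparable to its mean, which rules out a symmetric Gaussian on positive
#' support); flapping frequency is Gaussian. The two are coupled by a
#' Gaussian copula whose latent correlation is solved in closed form so that
#' the *output* Pearson correlation equals `dur_freq_corr`.
#'
#' @param grid_frequencies Stimulus frequencies F (Hz) of the trial grid.
#' @param grid_voltages Stimulus voltage amplitudes U (V) of the trial grid.
#' @param f_opt,u_opt Location of the initiation-probability peak (Hz, V).
#' @param f_width,u_width Log-space widths of the two Gaussian bumps.
#' @param peak_prob Initiation probability at the peak, in \[0, 1\].
#' @param freq_mean,freq_sd Mean and SD of flapping frequency (Hz).
#' @param dur_mean,dur_sd Mean and SD of flapping duration (ms).
#' @param dur_freq_corr Target Pearson correlation between duration and
#'   frequency on successful trials, in \[-1, 1\].
#' @param trials_per_cell Number of trials per (F, U) cell.
#' @param duty_ratio Stimulus duty ratio, in (0, 1).
#' @param polarity Stimulus polarity, `"bipolar"` or `"unipolar"`.
#' @param stim_duration_s Stimulus duration (s).
#' @param seed Integer seed.
#'
#' @return A list of class `behavior_gen_config`.
#' @seealso [generate_behavior_trials()], [initiation_probability()]
#' @export
behavior_gen_config <- function(grid_frequencies = c(3, 20, 40, 60, 80, 100),
                                grid_voltages = 3:8,
                                f_opt = 60, u_opt = 7,
                                f_width = 0.8, u_width = 0.35,
                                peak_prob = 0.85,
                                freq_mean = 120.657, freq_sd = 20.225,
                                dur_mean = 448.143, dur_sd = 411.659,
                                dur_freq_corr = -0.35,
                                trials_per_cell = 30,
                                duty_ratio = 0.4,
                                polarity = c("bipolar", "unipolar"),
                                stim_duration_s = 1,
                                seed = 1) {
  polarity <- match.arg(polarity)
  cfg <- list(grid_frequencies = as.numeric(grid_frequencies),
              grid_voltages = as.numeric(grid_voltages),
              f_opt = f_opt, u_opt = u_opt,
              f_width = f_width, u_width = u_width, peak_prob = peak_prob,
              freq_mean = freq_mean, freq_sd = freq_sd,
              dur_mean = dur_mean, dur_sd = dur_sd,
              dur_freq_corr = dur_freq_corr,
              trials_per_cell = trials_per_cell,
              duty_ratio = duty_ratio, polarity = polarity,
              stim_duration_s = stim_duration_s, seed = seed)
  validate_behavior_gen_config(cfg)
  structure(cfg, class = "behavior_gen_config")
}

validate_behavior_gen_config <- function(cfg) {
  if (length(cfg$grid_frequencies) < 1L || length(cfg$grid_voltages) < 1L) {
    stop_invalid("the stimulation grid must have at least one frequency and one voltage")
  }
  if (any(cfg$grid_frequencies <= 0) || any(cfg$grid_voltages <= 0)) {
    stop_invalid("grid frequencies and voltages must be positive")
  }
  if (cfg$peak_prob < 0 || cfg$peak_prob > 1) {
    stop_invalid("peak_prob must lie in [0, 1]")
  }
  if (cfg$dur_freq_corr < -1 || cfg$dur_freq_corr > 1) {
    stop_invalid("dur_freq_corr must lie in [-1, 1]")
  }
  if (cfg$freq_sd <= 0 || cfg$dur_sd <= 0) {
    stop_invalid("freq_sd and dur_sd must be positive")
  }
  if (cfg$dur_mean <= 0) stop_invalid("dur_mean must be positive (ms)")
  if (cfg$duty_ratio <= 0 || cfg$duty_ratio >= 1) {
    stop_invalid("duty_ratio must lie in (0, 1)")
  }
  if (cfg$trials_per_cell < 0) stop_invalid("trials_per_cell must be >= 0")
  invisible(cfg)
}

#' Flight-initiation probability surface
#'
#' Evaluates the unimodal success-probability surface of a
#' [behavior_gen_config()] at stimulus frequency `f` (Hz) and voltage `u`
#' (V). The surface peaks at (`f_opt`, `u_opt`) with value `peak_prob` and
#' decays as a Gaussian in log-stimulus space.
#'
#' @param config A [behavior_gen_config()].
#' @param f,u Stimulus frequency (Hz) and voltage amplitude (V); recycled.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' cfg <- behavior_gen_config()
#' initiation_probability(cfg, 60, 7)   # the peak
#' initiation_probability(cfg, 3, 3)    # far from it
initiation_probability <- function(config, f, u) {
  if (!inherits(config, "behavior_gen_config")) {
    config <- do.call(behavior_gen_config, config)
  }
  config$peak_prob *
    exp(-(log(f / config$f_opt))^2 / (2 * config$f_width^2) -
          (log(u / config$u_opt))^2 / (2 * config$u_width^2))
}

# Lognormal(mu, sigma) parameters matching a target mean/sd.
lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Latent Gaussian-copula correlation giving Pearson r between a lognormal
# (exp(mu + sigma Z1)) and a Gaussian variable: r = rho * sigma / sqrt(e^{sigma^2}-1).
copula_rho <- function(r_target, sigma) {
  rho <- r_target * sqrt(exp(sigma^2) - 1) / sigma
  if (abs(rho) > 1) {
    stop_invalid("dur_freq_corr is not attainable with this duration mean/SD ",
                 "(required latent correlation ", signif(rho, 4), ")")
  }
  rho
}

#' Generate a table of synthetic stimulation trials
#'
#' For every cell of the (frequency, voltage) stimulation grid, draws
#' `trials_per_cell` Bernoulli flight-initiation outcomes with probability
#' from [initiation_probability()]. Successful trials carry a flapping
#' frequency and duration drawn from the correlated bivariate response model
#' (Gaussian frequency, lognormal duration, Gaussian copula); unsuccessful
#' trials carry `NA` responses.
#'
#' @param config A [behavior_gen_config()].
#'
#' @return A `data.frame` with one row per trial and columns
#'   `stim_freq_hz`, `stim_voltage_v`, `duty_ratio`, `polarity`,
#'   `stim_duration_s`, `initiated` (logical), `flap_freq_hz`, `flap_dur_ms`.
#' @export
#' @examples
#' trials <- generate_behavior_trials(behavior_gen_config(trials_per_cell = 5))
#' head(trials)
generate_behavior_trials <- function(config = behavior_gen_config()) {
  if (!inherits(config, "behavior_gen_config")) {
    config <- do.call(behavior_gen_config, config)
  }
  validate_behavior_gen_config(config)

  grid <- expand.grid(stim_freq_hz = config$grid_frequencies,
                      stim_voltage_v = config$grid_voltages,
                      KEEP.OUT.ATTRS = FALSE)
  k <- config$trials_per_cell
  n <- nrow(grid) * k
  lp <- lognormal_params(config$dur_mean, config$dur_sd)
  rho <- copula_rho(config$dur_freq_corr, lp$sigma)

  trials <- with_seed(config$seed, {
    f <- rep(grid$stim_freq_hz, each = k)
    u <- rep(grid$stim_voltage_v, each = k)
    p <- initiation_probability(config, f, u)
    initiated <- stats::rbinom(n, 1L, p) == 1L
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    dur <- exp(lp$mu + lp$sigma * z1)
    freq <- config$freq_mean + config$freq_sd * z2
    data.frame(stim_freq_hz = f, stim_voltage_v = u,
               duty_ratio = config$duty_ratio, polarity = config$polarity,
               stim_duration_s = config$stim_duration_s,
               initiated = initiated,
               flap_freq_hz = ifelse(initiated, freq, NA_real_),
               flap_dur_ms = ifelse(initiated, dur, NA_real_))
  })
  attr(trials, "config") <- unclass(config)
  trials
}
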