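#' Sample from a doubly truncated discrete power law
#'
#' i.i.d. draws from P(s) proportional to s^-alpha on the integers
#' [s_min, s_max], by inverse CDF on the normalized pmf.
#'
#' @param alpha exponent (any real; alpha = 0 gives the uniform law).
#' @param s_min,s_max truncation bounds (s_min <= s_max).
#' @param n number of draws.
#' @param seed RNG seed; draws are deterministic given the seed.
#' @return integer vector of length `n`.
#' @examples
#' s <- sample_discrete_powerlaw(1.5, 1, 100, 1000, seed = 1)
#' range(s)
#' @export
sample_discrete_powerlaw <- function(alpha, s_min, s_max, n, seed = 1L) {
  if (s_min > s_max) stop("invalid range: s_min > s_max", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  cdf <- cumsum(powerlaw_pmf(alpha, s_min, s_max))
  with_seed(seed, {
    u <- stats::runif(n)
    s <- s_min + findInterval(u, cdf)
    s[s > s_max] <- s_max
    as.integer(s)
  })
}

#' Ensemble of independent Poisson spike trains
#'
#' Ground-truth fixture: every neuron in every trial fires as an independent
#' (in)homogeneous Poisson process with the given rate function, so CV = 1
#' and FF = 1 hold by construction and the PSTH estimates the rate function.
#'
#' @param rate_fn vectorized rate function of time in ms (spikes/second), or
#'   a single number for a homogeneous process.
#' @param n_neurons,n_trials ensemble dimensions.
#' @param t_lo,t_hi window (ms).
#' @param dt thinning step (ms).
#' @param seed base seed; trial k, neuron i uses an offset stream.
#' @return a `trial_ensemble` with rasters only (no traces).
#' @export
gen_poisson_ensemble <- function(rate_fn, n_neurons, n_trials, t_lo, t_hi,
                                 dt = 0.1, seed = 1L) {
  if (is.numeric(rate_fn)) {
    r0 <- rate_fn
    rate_fn <- function(t) rep_len(r0, length(t))
  }
  steps <- seq(t_lo, t_hi - dt / 2, by = dt)
  p <- rate_fn(steps) * dt / 1000
  if (any(p >= 0.1)) stop("rate * dt >= 0.1", call. = FALSE)
  rasters <- with_seed(seed, lapply(seq_len(n_trials), function(k) {
    hits <- which(matrix(stats::runif(length(steps) * n_neurons),
                         ncol = n_neurons) < p, arr.ind = TRUE)
    new_spike_raster(neuron = hits[, 2],
                     time = steps[hits[, 1]],
                     n_neurons = n_neurons, t_start = t_lo, t_end = t_hi,
                     trial_id = k)
  }))
  structure(list(rasters = rasters, traces = NULL, config = NULL,
                 bg = NULL, stim = NULL,
                 seeds = seed + seq_len(n_trials) - 1L,
                 t_pre = -t_lo, t_post = t_hi),
            class = "trial_ensemble")
}

#' Gated-tone trial set
#'
#' LFP-like fixture for time-frequency tests: a sinusoid present only inside
#' the gate window, plus white Gaussian noise. The known gate gives a ground
#' truth for band-power (synthetic desynchronization) tests.
#'
#' @param freq tone frequency (Hz), below fs/2.
#' @param amplitude tone amplitude.
#' @param gate_lo,gate_hi gate window (ms).
#' @param noise_sd white-noise SD.
#' @param fs sampling rate (Hz).
#' @param t_lo,t_hi trace window (ms).
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @return list with `times` (ms) and `signals` (time x trial matrix).
#' @export
gen_gated_tone <- function(freq, amplitude = 1, gate_lo, gate_hi,
                           noise_sd = 0, fs = 1000, t_lo = -1000,
                           t_hi = 1000, n_trials = 1, seed = 1L) {
  if (freq >= fs / 2) stop("tone frequency above Nyquist", call. = FALSE)
  times <- seq(t_lo, t_hi, by = 1000 / fs)
  tone <- amplitude * sin(2 * pi * freq * times / 1000)
  tone[times < gate_lo | times > gate_hi] <- 0
  signals <- with_seed(seed, {
    vapply(seq_len(n_trials), function(k)
      tone + stats::rnorm(length(times), 0, noise_sd),
      numeric(length(times)))
  })
  list(times = times, signals = signals)
}

#' Brute-force grid MLE for the truncated discrete power law
#'
#' Independent oracle for [fit_truncated_powerlaw()]: evaluates the exact
#' log-likelihood at every exponent of `alpha_grid` and returns the argmax
#' (ties broken to the smallest grid value). Used in tests only.
#'
#' @param sizes integer sample.
#' @param s_min,s_max fixed truncation range.
#' @param alpha_grid exponent grid.
#' @return the grid exponent maximizing the likelihood.
#' @export
brute_force_powerlaw_mle <- function(sizes, s_min, s_max,
                                     alpha_grid = seq(0.5, 4, by = 0.01)) {
  sizes <- sizes[sizes >= s_min & sizes <= s_max]
  slog <- sum(log(sizes))
  ll <- vapply(alpha_grid, function(a)
    -a * slog - length(sizes) * powerlaw_logz(a, s_min, s_max), 0)
  alpha_grid[which.max(ll)]
}
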