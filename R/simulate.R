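#' Background drive specification
#'
#' Each neuron independently receives a Poisson spike train at `rate`
#' spikes/second, delivered through an excitatory synapse (conductance jump
#' `dg_ex`). The default 20 Hz is the weak background that sustains ongoing
#' activity in the reference network.
#'
#' @param rate spikes/second per neuron (>= 0).
#' @param seed_offset added to the trial seed for the background stream.
#' @export
background_spec <- function(rate = 20, seed_offset = 0L) {
  if (rate < 0) stop("invalid `rate`: must be >= 0", call. = FALSE)
  structure(list(rate = rate, seed_offset = as.integer(seed_offset)),
            class = "background_spec")
}

#' Alpha-function stimulus specification
#'
#' The stimulus is an inhomogeneous Poisson input whose rate follows an alpha
#' function r(t) = a t exp(-t / tau_s) from stimulus onset, with
#' a = r_max e / tau_s so that the peak rate r_max is reached at t = tau_s.
#' Defaults r_max = 200 spikes/s, tau_s = 50 ms.
#'
#' @param r_max peak rate (spikes/second).
#' @param tau_s rise time of the alpha function (ms).
#' @param onset stimulus start time (ms).
#' @param duration length over which the rate function is applied (ms).
#' @param targets `"all"` to drive every neuron, `"excitatory"` to drive the
#'   excitatory population only.
#' @export
stimulus_spec <- function(r_max = 200, tau_s = 50, onset = 0, duration = 500,
                          targets = c("all", "excitatory")) {
  if (r_max < 0) stop("invalid `r_max`: must be >= 0", call. = FALSE)
  if (tau_s <= 0) stop("invalid `tau_s`: must be > 0", call. = FALSE)
  if (duration < 0) stop("invalid `duration`: must be >= 0", call. = FALSE)
  structure(list(r_max = r_max, tau_s = tau_s, onset = onset,
                 duration = duration, targets = match.arg(targets)),
            class = "stimulus_spec")
}

#' Alpha-function stimulus rate
#'
#' Evaluates r(t) = a (t - onset) exp(-(t - onset)/tau_s), a = r_max e/tau_s,
#' zero before onset. The rate is 0 at onset and peaks at r_max one rise time
#' later.
#'
#' @param t time (ms), vectorized.
#' @param stim a [stimulus_spec()].
#' @return rate in spikes/second.
#' @examples
#' s <- stimulus_spec(r_max = 200, tau_s = 50)
#' alpha_rate(50, s)   # 200, the peak
#' @export
alpha_rate <- function(t, stim) {
  u <- t - stim$onset
  r <- ifelse(u <= 0, 0, stim$r_max * exp(1) / stim$tau_s * u * exp(-u / stim$tau_s))
  r
}

#' Homogeneous Poisson spike train
#'
#' Bernoulli thinning on the integration grid: each step of width `dt`
#' contains a spike with probability `rate * dt`. Requires `rate * dt < 0.1`
#' so the discrete approximation of the Poisson process is adequate.
#'
#' @param rate spikes/second.
#' @param t_start,t_end window (ms).
#' @param dt step (ms).
#' @param seed RNG seed.
#' @return numeric vector of spike times in ms.
#' @export
poisson_train <- function(rate, t_start, t_end, dt = 0.1, seed = 1L) {
  inhomogeneous_poisson(function(t) rep_len(rate, length(t)),
                        t_start, t_end, dt, seed)
}

#' Inhomogeneous Poisson spike train
#'
#' Per-step Bernoulli with time-varying probability `rate_fn(t) * dt`;
#' the expected spike count is the integral of the rate over the window.
#'
#' @param rate_fn vectorized function of time (ms) returning spikes/second.
#' @inheritParams poisson_train
#' @export
inhomogeneous_poisson <- function(rate_fn, t_start, t_end, dt = 0.1,
                                  seed = 1L) {
  if (t_end <= t_start) return(numeric(0))
  steps <- seq(t_start, t_end - dt / 2, by = dt)
  p <- rate_fn(steps) * dt / 1000
  if (any(p < 0)) stop("negative rate", call. = FALSE)
  if (any(p >= 0.1))
    stop("rate * dt >= 0.1: time step too coarse for Bernoulli thinning",
         call. = FALSE)
  with_seed(seed, steps[stats::runif(length(steps)) < p])
}

new_spike_raster <- function(neuron, time, n_neurons, t_start, t_end,
                             trial_id = 1L, alignment = 0) {
  structure(list(neuron = as.integer(neuron), time = as.numeric(time),
                 n_neurons = as.integer(n_neurons), t_start = t_start,
                 t_end = t_end, trial_id = as.integer(trial_id),
                 alignment = alignment),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> trial %d: %d spikes, %d neurons, t in [%g, %g) ms\n",
    x$trial_id, length(x$time), x$n_neurons, x$t_start, x$t_end))
  invisible(x)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d samples at %g ms, t from %g ms\n",
              length(x$lfp), x$dt_record, x$t_start))
  invisible(x)
}

new_trace_set <- function(i_ex, i_inh, dt_record, t_start) {
  structure(list(i_ex = i_ex, i_inh = i_inh, lfp = abs(i_ex) + abs(i_inh),
                 dt_record = dt_record, t_start = t_start),
            class = "trace_set")
}

#' Simulate one trial of the network
#'
#' Integrates the conductance-based LIF network by exponential Euler at step
#' `config$dt`: synaptic conductances decay exponentially (tau_ex, tau_inh)
#' and jump by dg_ex / dg_inh on presynaptic spikes, which take effect at the
#' next step; a threshold crossing emits a spike, resets V to `v_reset` and
#' clamps it for the refractory period. Background and (optional)
#' alpha-function stimulus spikes are delivered to every neuron through
#' excitatory synapses. Initial potentials are drawn uniformly in
#' [v_rest, v_thresh) and a warm-up period is simulated and discarded before
#' recording starts.
#'
#' Recorded traces are the population means of the excitatory synaptic
#' current g_ex (E_ex - V) and inhibitory current g_inh (E_inh - V), averaged
#' within bins of `record_dt`; the LFP proxy is |I_ex| + |I_inh|.
#'
#' @param conn a [build_network()] connectivity.
#' @param config a [network_config()]; `conn` must match `config$n_neurons`.
#' @param bg a [background_spec()].
#' @param stim a [stimulus_spec()] or `NULL` for ongoing activity.
#' @param duration recorded duration (ms). Recording starts at time
#'   `-t_pre` relative to stimulus onset (at 0) when `stim` is given,
#'   at 0 otherwise.
#' @param record_traces record synaptic-current traces and LFP.
#' @param seed trial RNG seed.
#' @param warmup_ms discarded warm-up (ms), default 2000.
#' @param t_pre recorded time before stimulus onset (ms); only used with a
#'   stimulus.
#' @param record_dt trace sampling interval (ms), default 1.
#' @param delay_ms synaptic transmission delay (ms); 0 means spikes take
#'   effect at the next integration step.
#' @param record_v also record every neuron's membrane potential at
#'   `record_dt` (matrix `trace$v`, time by neuron); memory-heavy for long
#'   runs.
#' @param v_init initial membrane potentials (mV); default drawn uniformly
#'   in `[v_rest, v_thresh)`.
#' @return list with elements `raster` (a `spike_raster`) and `trace`
#'   (a `trace_set`, or `NULL` if not recorded).
#' @examples
#' cfg <- network_config(n_neurons = 100, dg_ex = 0.4)
#' conn <- build_network(cfg, seed = 1)
#' tr <- run_trial(conn, cfg, background_spec(20), NULL, duration = 1000,
#'                 seed = 1, warmup_ms = 200)
#' tr$raster
#' @export
run_trial <- function(conn, config, bg = background_spec(), stim = NULL,
                      duration = 10000, record_traces = TRUE, seed = 1L,
                      warmup_ms = 2000, t_pre = 0, record_dt = 1,
                      delay_ms = 0, record_v = FALSE, v_init = NULL) {
  validate_network_config(config)
  if (conn$n_neurons != config$n_neurons &&
      conn$n_neurons %% config$n_neurons != 0)
    stop("connectivity size does not match config$n_neurons", call. = FALSE)
  dt <- config$dt
  n <- conn$n_neurons
  t0 <- if (is.null(stim)) 0 else -t_pre
  n_steps <- as.integer(round(duration / dt))
  warmup_steps <- as.integer(round(warmup_ms / dt))
  record_every <- max(1L, as.integer(round(record_dt / dt)))

  p_stim <- numeric(0)
  if (!is.null(stim)) {
    tt <- t0 + (seq_len(n_steps) - 1) * dt
    r <- alpha_rate(tt, stim)
    r[tt >= stim$onset + stim$duration] <- 0
    p_stim <- r * dt / 1000
  }

  adj <- adjacency_csr(conn)
  res <- with_seed(seed + (if (is.null(bg)) 0L else bg$seed_offset), {
    v0 <- if (is.null(v_init))
      stats::runif(n, config$v_rest, config$v_thresh)
    else rep_len(v_init, n)
    .sim_lif_cpp(adj$targets, adj$offsets,
                 conn$is_excitatory, v0,
                 config[c("dt", "tau_m", "tau_ex", "tau_inh", "v_rest",
                          "v_thresh", "v_reset", "e_ex", "e_inh", "t_ref",
                          "dg_ex", "dg_inh")],
                 if (is.null(bg)) 0 else bg$rate, p_stim,
                 n_steps, warmup_steps, record_traces, record_every,
                 max(1L, as.integer(round(delay_ms / dt))),
                 if (!is.null(stim) && identical(stim$targets, "excitatory"))
                   sum(conn$is_excitatory) else 0L,
                 record_v)
  })
  raster <- new_spike_raster(res$neuron, res$time + t0, n,
                             t_start = t0, t_end = t0 + duration,
                             alignment = 0)
  trace <- if (record_traces)
    new_trace_set(res$i_ex, res$i_inh, record_dt, t_start = t0) else NULL
  if (record_v && !is.null(trace)) trace$v <- res$v
  list(raster = raster, trace = trace)
}

#' Simulate an ensemble of stimulus-aligned trials
#'
#' Runs `n_trials` independent trials with seeds `base_seed + k`, each
#' recorded from `-t_pre` to `+t_post` with the stimulus onset at time 0 and
#' a discarded warm-up before the recording window.
#'
#' @param n_trials number of trials (>= 1).
#' @param conn,config,bg,stim as in [run_trial()].
#' @param t_pre,t_post recorded time before/after stimulus onset (ms).
#' @param base_seed trial k uses seed `base_seed + k - 1`.
#' @param warmup_ms discarded warm-up per trial (ms).
#' @param record_dt trace sampling interval (ms).
#' @return An object of class `trial_ensemble`: lists `rasters` and `traces`,
#'   shared `config`, `bg`, `stim`, and the per-trial seeds.
#' @export
run_ensemble <- function(n_trials, conn, config, bg = background_spec(),
                         stim = stimulus_spec(), t_pre = 1000, t_post = 1000,
                         base_seed = 1L, warmup_ms = 2000, record_dt = 1) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  seeds <- base_seed + seq_len(n_trials) - 1L
  rasters <- vector("list", n_trials)
  traces <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    tr <- run_trial(conn, config, bg, stim, duration = t_pre + t_post,
                    record_traces = TRUE, seed = seeds[k],
                    warmup_ms = warmup_ms, t_pre = t_pre,
                    record_dt = record_dt)
    tr$raster$trial_id <- k
    rasters[[k]] <- tr$raster
    traces[[k]] <- tr$trace
  }
  structure(list(rasters = rasters, traces = traces, config = config,
                 bg = bg, stim = stim, seeds = seeds,
                 t_pre = t_pre, t_post = t_post),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d trials, t in [%g, %g] ms around onset\n",
              length(x$rasters), -x$t_pre, x$t_post))
  invisible(x)
}

#' Screen a realization for the degenerate high-rate asynchronous mode
#'
#' Finite networks in the critical coupling regime are occasionally
#' initialized into a high-rate, low-synchrony irregular mode without
#' power-law avalanches. Such realizations are excluded from criticality
#' analyses. The screen flags a realization when the population-rate
#' fluctuation index (SD of the 10-ms-binned population rate divided by its
#' mean) falls below `chi_min` while the mean rate per neuron exceeds
#' `rate_max`. A silent realization is reported separately. The default
#' thresholds sit between the two empirically observed modes at the
#' reference parameters: the critical quiet-burst mode (index ~2, rate
#' ~3.4 spikes/s) and the asynchronous mode (index 0.5-0.8, rate ~13
#' spikes/s).
#'
#' @param raster a `spike_raster` covering at least 5 s.
#' @param trace optional `trace_set` (diagnostics only).
#' @param chi_min fluctuation-index threshold (default 1.0).
#' @param rate_max mean-rate threshold in spikes/s per neuron (default 8).
#' @param bin_ms population-rate bin (ms).
#' @return list with `degenerate` (flag), `silent` (flag), `chi`
#'   (fluctuation index), `mean_rate` (spikes/s per neuron).
#' @export
is_degenerate_state <- function(raster, trace = NULL, chi_min = 1.0,
                                rate_max = 8, bin_ms = 10) {
  span <- raster$t_end - raster$t_start
  if (span < 5000)
    stop("window too short: need >= 5 s of activity", call. = FALSE)
  n_bins <- floor(span / bin_ms)
  mean_rate <- length(raster$time) / raster$n_neurons / (span / 1000)
  if (length(raster$time) == 0)
    return(list(degenerate = FALSE, silent = TRUE, chi = NA_real_,
                mean_rate = 0))
  b <- floor((raster$time - raster$t_start) / bin_ms) + 1
  counts <- tabulate(b[b <= n_bins], nbins = n_bins)
  chi <- stats::sd(counts) / mean(counts)
  list(degenerate = is.finite(chi) && chi < chi_min && mean_rate > rate_max,
       silent = mean_rate < 0.01,
       chi = chi, mean_rate = mean_rate)
}
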