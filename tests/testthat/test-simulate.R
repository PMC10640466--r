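test_that("alpha-function rate has the right shape and closed-form values", {
  s <- stimulus_spec(r_max = 200, tau_s = 50, onset = 0)
  expect_equal(alpha_rate(0, s), 0)
  expect_equal(alpha_rate(50, s), 200)            # peak r_max at t = tau_s
  expect_equal(alpha_rate(100, s), 400 / exp(1), tolerance = 1e-12)
  expect_equal(alpha_rate(-10, s), 0)
  s2 <- stimulus_spec(r_max = 200, tau_s = 50, onset = 300)
  expect_equal(alpha_rate(350, s2), 200)
})

test_that("homogeneous Poisson train has Poisson count and CV 1", {
  expect_length(poisson_train(0, 0, 1000, seed = 1), 0)
  tt <- poisson_train(20, 0, 100e3, dt = 0.1, seed = 2)
  expect_lt(abs(length(tt) - 2000), 4 * sqrt(2000))
  tt_long <- poisson_train(20, 0, 500e3, dt = 0.1, seed = 3)
  expect_equal(isi_cv(diff(tt_long)), 1, tolerance = 0.05)
  expect_error(poisson_train(20, 0, 100, dt = 10), "0.1")
})

test_that("inhomogeneous Poisson matches its rate integral", {
  # constant rate reduces to the homogeneous case
  a <- inhomogeneous_poisson(function(t) rep(20, length(t)), 0, 50e3,
                             seed = 4)
  b <- poisson_train(20, 0, 50e3, seed = 4)
  expect_identical(a, b)
  expect_length(inhomogeneous_poisson(function(t) rep(10, length(t)),
                                      100, 100), 0)

  # alpha-function stimulus: expected count = integral of the rate
  s <- stimulus_spec(r_max = 200, tau_s = 50)
  grid <- seq(0, 500, by = 0.01)
  expected <- sum(alpha_rate(grid, s)) * 0.01 / 1000  # quadrature, ~27.2
  counts <- vapply(1:40, function(k)
    length(inhomogeneous_poisson(function(t) alpha_rate(t, s), 0, 500,
                                 seed = 100 + k)), 0)
  expect_lt(abs(mean(counts) - expected), 4 * sqrt(expected / 40))
})

test_that("a quiescent unconnected network stays at rest with zero LFP", {
  cfg <- small_config()
  conn <- build_network(cfg, seed = 1)
  tr <- run_trial(conn, cfg, background_spec(0), NULL, duration = 1000,
                  seed = 1, warmup_ms = 100, record_v = TRUE,
                  v_init = cfg$v_rest)
  expect_length(tr$raster$time, 0)
  expect_true(all(tr$trace$lfp == 0))
  expect_true(all(tr$trace$v == cfg$v_rest))
})

test_that("subthreshold integration matches the exact ODE solution", {
  skip_if_not_installed("deSolve")
  # one isolated neuron relaxing from -52 mV with an excitatory conductance
  # g(0) = 0.5 decaying with tau_ex; compare against a stiff ODE solve.
  # The conductance is injected by a guaranteed background spike in the
  # first step (rate chosen so p = dt * rate / 1000 ~ 0.09, retry seeds
  # until the spike lands in step one and no other spike occurs).
  cfg <- network_config(n_neurons = 2L, frac_excitatory = 0.5,
                        density = 0, dg_ex = 0.5, dg_inh = 5)
  conn <- build_network(cfg, seed = 1)
  # no-background run from a supra-rest start: pure leak relaxation
  tr <- run_trial(conn, cfg, background_spec(0), NULL, duration = 100,
                  seed = 1, warmup_ms = 0, record_v = TRUE, record_dt = 1,
                  v_init = -52)
  # sample k is recorded after the update of step (k-1)*10, i.e. at time
  # (k-1)*record_dt + dt
  t_ms <- (seq_len(nrow(tr$trace$v)) - 1) * 1 + cfg$dt
  exact <- -60 + (-52 + 60) * exp(-t_ms / cfg$tau_m)
  expect_equal(tr$trace$v[, 1], exact, tolerance = 1e-5)

  # with a clamped-at-start conductance transient, via deSolve oracle:
  # emulate by initializing V at rest and driving neuron 1 with a short
  # strong stimulus step is stochastic; instead check the conductance decay
  # path through the synaptic current traces after a forced presynaptic
  # spike: neuron 1 -> neuron 2 with dg_ex = 0.5
  cfg2 <- network_config(n_neurons = 2L, frac_excitatory = 0.9,
                         density = 0, dg_ex = 0.5)
  conn2 <- build_network(cfg2, seed = 1)
  conn2$edges <- cbind(pre = 1L, post = 2L)
  tr2 <- run_trial(conn2, cfg2, background_spec(0), NULL, duration = 60,
                   seed = 1, warmup_ms = 0, record_v = TRUE, record_dt = 0.1,
                   v_init = c(-49, -60))
  # neuron 1 starts above threshold and fires on the first step, so
  # neuron 2 receives exactly one EPSP with known onset
  spike_t <- tr2$raster$time[tr2$raster$neuron == 1][1]
  expect_lt(spike_t, 0.3)
  ode <- deSolve::ode(
    y = c(v = -60), times = seq(0, 55, by = 0.1),
    func = function(t, y, p) {
      g <- 0.5 * exp(-t / cfg2$tau_ex)
      list((-60 - y[1] + g * (0 - y[1])) / cfg2$tau_m)
    }, parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  # sample k holds V after k steps; the EPSP is delivered at the start of
  # the step after the spike, so the first depolarized sample corresponds
  # to one dt of the ODE solution
  v2 <- tr2$trace$v[, 2]
  onset_idx <- which(diff(v2) > 1e-9)[1] + 1L  # first depolarized sample
  n_cmp <- 500
  # exp-Euler holds g constant per 0.1-ms step, so allow ~0.1 mV of
  # discretization error against the continuous solution
  expect_equal(v2[onset_idx - 1 + seq_len(n_cmp)],
               ode[1 + seq_len(n_cmp), "v"], tolerance = 2e-3,
               ignore_attr = TRUE)
  # EPSP peak amplitude ~ 6.5 mV for dg 0.5 at rest
  expect_equal(max(v2) - (-60), max(ode[, "v"]) + 60, tolerance = 0.01)
})

test_that("spike propagation is causal and conservative on a chain", {
  # A -> B with a strong synapse: every A spike forces one B spike shortly
  # after; B receives nothing else
  cfg <- network_config(n_neurons = 2L, frac_excitatory = 0.9, density = 0,
                        dg_ex = 3)
  conn <- build_network(cfg, seed = 1)
  conn$edges <- cbind(pre = 1L, post = 2L)
  # drive A only: background targets all neurons, so instead start A above
  # threshold repeatedly via refractory-paced self-sustained firing is not
  # possible without input; use background and verify counts match closely
  tr <- run_trial(conn, cfg, background_spec(5), NULL, duration = 20000,
                  seed = 6, warmup_ms = 0, record_traces = FALSE,
                  v_init = cfg$v_rest)
  a <- sort(tr$raster$time[tr$raster$neuron == 1])
  b <- sort(tr$raster$time[tr$raster$neuron == 2])
  # every A spike elicits a B spike within 3 ms (dg 3 is far
  # suprathreshold) unless B is refractory from a recent spike of its own
  eligible <- vapply(a, function(t) !any(b > t - 5 & b <= t), TRUE)
  matched <- vapply(a, function(t) any(b > t & b <= t + 3), TRUE)
  expect_gt(length(a), 10)
  expect_true(all(matched[eligible]))
})

test_that("no neuron violates the refractory period", {
  tr <- critical_ongoing()
  isis <- isi_list(tr$raster, pooled = FALSE)
  min_isi <- min(vapply(isis, min, 0))
  expect_gte(min_isi, ref_config()$t_ref - 1e-9)
})

test_that("halving dt changes the ongoing rate by less than 5 percent", {
  cfg1 <- ref_config()
  cfg2 <- ref_config(dt = 0.05)
  conn <- ref_connectivity()
  r1 <- length(run_trial(conn, cfg1, background_spec(20), NULL,
                         duration = 60000, seed = 21,
                         record_traces = FALSE)$raster$time)
  r2 <- length(run_trial(conn, cfg2, background_spec(20), NULL,
                         duration = 60000, seed = 21,
                         record_traces = FALSE)$raster$time)
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("evoked rate is non-decreasing in stimulus strength", {
  conn <- ref_connectivity()
  cfg <- ref_config()
  evoked <- vapply(c(50, 100, 200, 400), function(rm) {
    ens <- run_ensemble(8, conn, cfg, background_spec(20),
                        stimulus_spec(r_max = rm), t_pre = 300,
                        t_post = 500, base_seed = 60, warmup_ms = 500)
    sum(vapply(ens$rasters, function(r) sum(r$time >= 0 & r$time <= 500), 0))
  }, 0)
  expect_true(all(diff(evoked) >= 0))
})

test_that("ensembles are deterministic and align trials", {
  cfg <- small_config()
  conn <- build_network(cfg, seed = 1)
  e1 <- run_ensemble(3, conn, cfg, background_spec(20), stimulus_spec(),
                     t_pre = 200, t_post = 200, base_seed = 5,
                     warmup_ms = 200)
  e2 <- run_ensemble(3, conn, cfg, background_spec(20), stimulus_spec(),
                     t_pre = 200, t_post = 200, base_seed = 5,
                     warmup_ms = 200)
  expect_identical(e1$rasters, e2$rasters)
  expect_identical(e1$traces, e2$traces)
  # single-trial ensemble: ERP equals that trial's LFP
  e3 <- run_ensemble(1, conn, cfg, background_spec(20), stimulus_spec(),
                     t_pre = 200, t_post = 200, base_seed = 9,
                     warmup_ms = 200)
  expect_equal(compute_erp(e3)$erp, e3$traces[[1]]$lfp)
})

test_that("degenerate-state screen separates modes", {
  # silent raster: silent, not the high-rate mode
  silent <- toy_raster(integer(0), numeric(0), n_neurons = 100,
                       t_start = 0, t_end = 6000)
  st <- is_degenerate_state(silent)
  expect_true(st$silent)
  expect_false(st$degenerate)

  # independent Poisson surrogate at 30 Hz/neuron: flagged
  ens <- gen_poisson_ensemble(30, n_neurons = 500, n_trials = 1,
                              t_lo = 0, t_hi = 8000, dt = 0.5, seed = 3)
  st2 <- is_degenerate_state(ens$rasters[[1]])
  expect_true(st2$degenerate)
  expect_lt(st2$chi, 1)

  # critical-configuration realization: not flagged
  st3 <- is_degenerate_state(critical_ongoing()$raster)
  expect_false(st3$degenerate)
  expect_gt(st3$chi, 1)

  expect_error(is_degenerate_state(toy_raster(1L, 1, t_end = 100)), "short")
})
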