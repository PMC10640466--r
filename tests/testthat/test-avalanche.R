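test_that("avalanche segmentation matches the hand-traced oracle", {
  # per-bin spike counts [1,2,0,1,0,0,3] at bin width 1 ms
  r <- toy_raster(neuron = c(1, 1, 2, 1, 1, 2, 3),
                  time = c(0.1, 1.2, 1.7, 3.4, 6.1, 6.5, 6.9),
                  n_neurons = 3, t_start = 0, t_end = 7)
  av <- detect_avalanches(r, dt = 1)
  expect_equal(av$sizes, c(3L, 1L, 3L))
  expect_equal(av$durations, c(2L, 1L, 1L))

  # single spike: one avalanche of size 1
  av1 <- detect_avalanches(toy_raster(1, 5, t_start = 0, t_end = 10), dt = 1)
  expect_equal(av1$sizes, 1L)

  # every bin occupied: one avalanche with all spikes
  r2 <- toy_raster(rep(1, 10), seq(0.5, 9.5, by = 1), t_start = 0,
                   t_end = 10)
  av2 <- detect_avalanches(r2, dt = 1)
  expect_equal(av2$sizes, 10L)
  expect_equal(av2$durations, 10L)

  # empty raster: empty set
  expect_length(detect_avalanches(toy_raster(integer(0), numeric(0),
                                             n_neurons = 1, t_start = 0,
                                             t_end = 10))$sizes, 0)

  # distinct-neuron mode counts each neuron once per avalanche
  r3 <- toy_raster(c(1, 1, 2), c(0.1, 1.1, 1.5), n_neurons = 2,
                   t_start = 0, t_end = 3)
  expect_equal(detect_avalanches(r3, dt = 1)$sizes, 3L)
  expect_equal(detect_avalanches(r3, dt = 1, distinct_neurons = TRUE)$sizes,
               2L)
})

test_that("avalanche sizes conserve the total spike count", {
  tr <- critical_ongoing()
  av <- detect_avalanches(tr$raster, dt = 0.1)
  expect_equal(sum(av$sizes), length(tr$raster$time))
  ens <- gen_poisson_ensemble(5, 50, 1, 0, 10000, dt = 0.5, seed = 2)
  av2 <- detect_avalanches(ens$rasters[[1]], dt = 0.5)
  expect_equal(sum(av2$sizes), length(ens$rasters[[1]]$time))
})

test_that("size distribution counts correctly and matches the analytic pmf", {
  d <- size_distribution(c(1, 1, 2))
  expect_equal(d$prob[d$size == 1], 2 / 3)
  expect_equal(d$prob[d$size == 2], 1 / 3)
  expect_equal(sum(size_distribution(c(3, 3, 3))$prob), 1)
  expect_equal(size_distribution(c(7, 7))$prob, 1)
  expect_error(size_distribution(integer(0)), "empty")

  s <- sample_discrete_powerlaw(1.5, 1, 100, 1e5, seed = 4)
  emp <- size_distribution(s)
  pmf <- critnet:::powerlaw_pmf(1.5, 1, 100)
  ref <- pmf[emp$size]
  expect_lt(max(abs(emp$prob - ref)), 0.01)
})

test_that("truncated power-law MLE recovers the exponent", {
  s <- sample_discrete_powerlaw(1.5, 1, 300, 1e5, seed = 8)
  fit <- fit_truncated_powerlaw(s, seed = 3)
  expect_true(fit$accepted)
  expect_equal(fit$alpha, 1.5, tolerance = 0.05)

  # agreement with the brute-force grid oracle on a fixed range
  s2 <- sample_discrete_powerlaw(2.0, 2, 200, 1e4, seed = 9)
  a_opt <- critnet:::powerlaw_mle(s2[s2 >= 2 & s2 <= 200], 2, 200)
  a_grid <- brute_force_powerlaw_mle(s2, 2, 200,
                                     alpha_grid = seq(0.5, 4, by = 0.01))
  expect_lt(abs(a_opt - a_grid), 0.011)
})

test_that("subsampling a power-law sample leaves the exponent stable", {
  s <- sample_discrete_powerlaw(1.5, 1, 300, 4e4, seed = 12)
  half <- s[seq(1, length(s), by = 2)]
  f1 <- fit_truncated_powerlaw(s, seed = 5)
  f2 <- fit_truncated_powerlaw(half, seed = 5)
  # standard error of alpha-hat ~ (alpha-1)/sqrt(n) scale; use a generous
  # bound of 3 combined SEs
  se <- (f1$alpha - 1) * sqrt(1 / f1$n_tail + 1 / f2$n_tail)
  expect_lt(abs(f1$alpha - f2$alpha), max(3 * se, 0.05))
})

test_that("geometric data admit no wide power-law range", {
  # exponential decay curves away from any power law over a wide range;
  # only narrow windows (where curvature is invisible) could ever pass,
  # so the candidate ranges here span at least a factor of five
  g <- critnet:::with_seed(31, stats::rgeom(20000, 0.5) + 1L)
  fit <- fit_truncated_powerlaw(g, s_min_grid = 1:2,
                                s_max_grid = c(10, max(g)), seed = 7)
  expect_false(fit$accepted)
  # while a genuine power-law sample on the same support is accepted
  s <- sample_discrete_powerlaw(2, 1, 16, 20000, seed = 8)
  fit2 <- fit_truncated_powerlaw(s, s_min_grid = 1:2,
                                 s_max_grid = c(10, 16), seed = 9)
  expect_true(fit2$accepted)
})

test_that("surrogate p-values behave as a goodness-of-fit probability", {
  s <- sample_discrete_powerlaw(1.6, 3, 150, 3000, seed = 15)
  fit <- list(alpha = critnet:::powerlaw_mle(s, 3, 150), s_min = 3,
              s_max = 150)
  # determinism
  p1 <- ks_pvalue(fit, s, n_surrogates = 100, seed = 42)
  p2 <- ks_pvalue(fit, s, n_surrogates = 100, seed = 42)
  expect_identical(p1, p2)
  expect_error(ks_pvalue(fit, s, n_surrogates = 10), "20")

  # self-consistency: data drawn from the fitted law give p spread over
  # (0, 1) with mean ~ 0.5
  ps <- vapply(1:20, function(k) {
    x <- sample_discrete_powerlaw(1.6, 3, 150, 1500, seed = 500 + k)
    f <- list(alpha = critnet:::powerlaw_mle(x, 3, 150), s_min = 3,
              s_max = 150)
    ks_pvalue(f, x, n_surrogates = 100, seed = 600 + k)
  }, 0)
  expect_lt(abs(mean(ps) - 0.5), 0.2)

  # grossly non-power-law data: all sizes equal -> p = 0
  f0 <- list(alpha = 1.5, s_min = 1, s_max = 50)
  expect_equal(ks_pvalue(f0, rep(25L, 500), n_surrogates = 50, seed = 1), 0)
})

test_that("power-law deviation is zero for exact laws and larger otherwise", {
  pmf <- data.frame(size = 1:100,
                    prob = critnet:::powerlaw_pmf(1.5, 1, 100))
  expect_lt(powerlaw_deviation(pmf, prob_floor = 0), 1e-20)

  # exponential pmf deviates more than the matching power law
  ex <- data.frame(size = 1:100, prob = dexp(1:100, 0.1) / sum(dexp(1:100, 0.1)))
  expect_gt(powerlaw_deviation(ex, prob_floor = 1e-12),
            powerlaw_deviation(pmf, prob_floor = 0))

  # invariance under rescaling all probabilities
  pmf2 <- pmf
  pmf2$prob <- pmf$prob * 7
  expect_equal(powerlaw_deviation(pmf2, prob_floor = 0),
               powerlaw_deviation(pmf, prob_floor = 0))

  expect_error(powerlaw_deviation(pmf[1:2, ]), "3")
})

test_that("E-I balance ratio has the right fixed points", {
  mk <- function(iex, iinh) critnet:::new_trace_set(iex, iinh, 1, 0)
  n <- 4000
  expect_equal(ei_balance_ratio(mk(rep(2, n), rep(0, n))), 1)
  expect_equal(ei_balance_ratio(mk(rep(2, n), rep(-2, n))), 0)
  expect_equal(ei_balance_ratio(mk(rep(4, n), rep(-2, n))), 0.5)
  expect_error(ei_balance_ratio(mk(rep(1, 100), rep(0, 100))), "window")
  expect_error(ei_balance_ratio(mk(rep(0, n), rep(0, n))), "silent")
})
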