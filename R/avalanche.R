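#' Detect neuronal avalanches in a spike raster
#'
#' Pools spikes over all neurons, bins time at width `dt` (the simulation
#' step by default) and takes every maximal run of consecutive occupied bins
#' as one avalanche; two avalanches are separated by at least one bin in
#' which no neuron fires. Avalanche size is the total spike count of the run
#' (a distinct-neuron count is available via `distinct_neurons = TRUE`).
#'
#' @param raster a `spike_raster`.
#' @param dt bin width (ms).
#' @param distinct_neurons count each neuron at most once per avalanche.
#' @return An object of class `avalanche_set`: integer vectors `sizes` and
#'   `durations` (in bins), plus `bin_width`.
#' @examples
#' r <- critnet:::new_spike_raster(c(1, 2, 1), c(0.0, 0.05, 0.25), 2, 0, 1)
#' detect_avalanches(r, dt = 0.1)$sizes  # 2 1
#' @export
detect_avalanches <- function(raster, dt = 0.1, distinct_neurons = FALSE) {
  if (length(raster$time) == 0)
    return(structure(list(sizes = integer(0), durations = integer(0),
                          bin_width = dt), class = "avalanche_set"))
  b <- floor((raster$time - raster$t_start) / dt)
  ord <- order(b)
  b <- b[ord]
  occ <- unique(b)                       # sorted occupied bins
  run_id_occ <- cumsum(c(1L, diff(occ) > 1))
  counts_per_bin <- tabulate(match(b, occ), nbins = length(occ))
  if (distinct_neurons) {
    nrn <- raster$neuron[ord]
    run_of_spike <- run_id_occ[match(b, occ)]
    sizes <- as.integer(tapply(nrn, run_of_spike,
                               function(x) length(unique(x))))
  } else {
    sizes <- as.integer(tapply(counts_per_bin, run_id_occ, sum))
  }
  durations <- as.integer(tapply(occ, run_id_occ, function(x) length(x)))
  structure(list(sizes = unname(sizes), durations = unname(durations),
                 bin_width = dt), class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("<avalanche_set> %d avalanches, sizes 1..%s, bin %g ms\n",
              length(x$sizes),
              if (length(x$sizes)) max(x$sizes) else "-", x$bin_width))
  invisible(x)
}

#' Empirical avalanche-size distribution
#'
#' @param av an `avalanche_set` (or a vector of sizes).
#' @return data.frame with columns `size` and `prob`; probabilities sum to 1.
#' @export
size_distribution <- function(av) {
  sizes <- if (inherits(av, "avalanche_set")) av$sizes else av
  if (length(sizes) == 0) stop("empty avalanche set", call. = FALSE)
  tab <- table(sizes)
  data.frame(size = as.integer(names(tab)),
             prob = as.numeric(tab) / length(sizes))
}

# log-pmf normalizer of P(s) = s^-alpha / Z on integers [s_min, s_max]
powerlaw_logz <- function(alpha, s_min, s_max) {
  log(sum(exp(-alpha * log(s_min:s_max))))
}

powerlaw_pmf <- function(alpha, s_min, s_max) {
  s <- s_min:s_max
  w <- exp(-alpha * log(s))
  w / sum(w)
}

# MLE of alpha on the truncated support by 1-D likelihood maximization
powerlaw_mle <- function(sizes, s_min, s_max, lower = 0.01, upper = 20) {
  mean_log <- mean(log(sizes))
  nll <- function(a) a * mean_log + powerlaw_logz(a, s_min, s_max)
  stats::optimize(nll, c(lower, upper))$minimum
}

# K-S distance between the empirical CDF of `sizes` (all within range) and
# the fitted truncated power-law CDF
powerlaw_ks <- function(sizes, alpha, s_min, s_max) {
  s <- s_min:s_max
  fit_cdf <- cumsum(powerlaw_pmf(alpha, s_min, s_max))
  emp_cdf <- cumsum(tabulate(sizes - s_min + 1L, nbins = length(s))) /
    length(sizes)
  max(abs(emp_cdf - fit_cdf))
}

#' Fit a doubly truncated discrete power law to avalanche sizes
#'
#' Searches truncation ranges [s_min, s_max]: for each candidate, the
#' exponent alpha of P(s) = s^-alpha / Z on the integers of the range is
#' estimated by maximum likelihood, and the Kolmogorov-Smirnov distance
#' between the fitted and empirical CDFs on the range is computed. Candidates
#' are visited widest range first (ties broken by smaller K-S distance), and
#' the first range whose truncation-based surrogate p-value (see
#' [ks_pvalue()]) exceeds `p_threshold` is selected. If no range passes, the
#' widest/smallest-K-S candidate is returned with `accepted = FALSE`,
#' signalling non-power-law data.
#'
#' @param sizes integer avalanche sizes (>= 100 samples).
#' @param s_min_grid candidate lower truncations (default 1..20).
#' @param s_max_grid candidate upper truncations (default: logarithmic grid
#'   up to the maximum observed size).
#' @param n_surrogates surrogate samples per p-value (default 200).
#' @param p_threshold acceptance threshold on the surrogate p (default 0.2).
#' @param min_tail minimum number of samples inside a candidate range.
#' @param seed RNG seed for the surrogate test.
#' @return An object of class `powerlaw_fit`: `alpha`, `s_min`, `s_max`,
#'   `n_tail`, `ks_stat`, `p_value`, `n_surrogates`, `accepted`.
#' @export
fit_truncated_powerlaw <- function(sizes, s_min_grid = 1:20,
                                   s_max_grid = NULL, n_surrogates = 200,
                                   p_threshold = 0.2, min_tail = 100,
                                   seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 100)
    stop("need >= 100 avalanche sizes to fit", call. = FALSE)
  smax_obs <- max(sizes)
  if (is.null(s_max_grid)) {
    s_max_grid <- unique(round(exp(seq(log(30), log(smax_obs),
                                       length.out = 12))))
    s_max_grid <- s_max_grid[s_max_grid <= smax_obs]
  }
  cand <- expand.grid(s_min = s_min_grid, s_max = s_max_grid)
  cand <- cand[cand$s_max > cand$s_min * 2, , drop = FALSE]
  if (nrow(cand) == 0) stop("no valid truncation candidates", call. = FALSE)

  fits <- lapply(seq_len(nrow(cand)), function(i) {
    lo <- cand$s_min[i]; hi <- cand$s_max[i]
    tail <- sizes[sizes >= lo & sizes <= hi]
    if (length(tail) < min_tail) return(NULL)
    a <- powerlaw_mle(tail, lo, hi)
    list(alpha = a, s_min = lo, s_max = hi, n_tail = length(tail),
         ks_stat = powerlaw_ks(tail, a, lo, hi))
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("no truncation range contains >= ", min_tail, " samples",
         call. = FALSE)
  width <- vapply(fits, function(f) log(f$s_max) - log(f$s_min), 0)
  ks <- vapply(fits, function(f) f$ks_stat, 0)
  ord <- order(-width, ks)
  fits <- fits[ord]

  best <- NULL
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    fit <- structure(c(f, list(p_value = NA_real_,
                               n_surrogates = n_surrogates,
                               accepted = FALSE)),
                     class = "powerlaw_fit")
    if (is.null(best)) best <- fit
    # surrogate refitting can only shrink K-S distances, so an observed
    # distance far above the classical large-sample quantile cannot pass
    if (f$ks_stat * sqrt(f$n_tail) > 2.5) next
    tail <- sizes[sizes >= f$s_min & sizes <= f$s_max]
    p <- ks_pvalue(fit, tail, n_surrogates, seed = seed + j)
    fit$p_value <- p
    if (p > p_threshold) {
      fit$accepted <- TRUE
      return(fit)
    }
    if (identical(best$p_value, NA_real_) || isTRUE(p > best$p_value))
      best <- fit
  }
  best
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.3f on [%d, %d], n = %d, KS = %.4f, p = %s%s\n",
    x$alpha, x$s_min, x$s_max, x$n_tail, x$ks_stat,
    if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value),
    if (x$accepted) "" else " (no acceptable range)"))
  invisible(x)
}

#' Truncation-based Kolmogorov-Smirnov surrogate p-value
#'
#' Draws `n_surrogates` samples of size `n_tail` from the fitted truncated
#' discrete power law, refits the exponent of each surrogate on the same
#' truncation range, and computes each surrogate's K-S distance to its own
#' refit. The p-value is the fraction of surrogate distances at least as
#' large as the observed one.
#'
#' @param fit a `powerlaw_fit` with a valid range.
#' @param sizes the observed sizes within the fit range.
#' @param n_surrogates number of surrogates (>= 20).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return p-value in [0, 1].
#' @export
ks_pvalue <- function(fit, sizes, n_surrogates = 200, seed = 1L) {
  if (n_surrogates < 20)
    stop("need >= 20 surrogates for a usable p-value resolution",
         call. = FALSE)
  sizes <- sizes[sizes >= fit$s_min & sizes <= fit$s_max]
  n <- length(sizes)
  obs <- powerlaw_ks(sizes, powerlaw_mle(sizes, fit$s_min, fit$s_max),
                     fit$s_min, fit$s_max)
  cdf <- cumsum(powerlaw_pmf(fit$alpha, fit$s_min, fit$s_max))
  ks_surr <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(k) {
      u <- stats::runif(n)
      surr <- fit$s_min + findInterval(u, cdf)
      surr[surr > fit$s_max] <- fit$s_max
      a <- powerlaw_mle(surr, fit$s_min, fit$s_max)
      powerlaw_ks(surr, a, fit$s_min, fit$s_max)
    }, 0)
  })
  mean(ks_surr >= obs)
}

#' Least-squares deviation from a power law in log-log space
#'
#' Restricts the empirical size distribution to probabilities above
#' `prob_floor` (discarding the exponential cutoff tail), fits a straight
#' line to (log10 size, log10 probability) by least squares, and returns the
#' mean squared residual. Smaller values mean closer to a power law; the
#' critical state minimizes this deviation.
#'
#' @param pmf data.frame with columns `size`, `prob` (from
#'   [size_distribution()]).
#' @param prob_floor probability floor (default 5e-5).
#' @return mean squared residual of the log-log fit.
#' @export
powerlaw_deviation <- function(pmf, prob_floor = 5e-5) {
  keep <- pmf$prob > prob_floor
  if (sum(keep) < 3)
    stop("fewer than 3 distribution points above the probability floor",
         call. = FALSE)
  x <- log10(pmf$size[keep])
  y <- log10(pmf$prob[keep])
  mean(stats::lm.fit(cbind(1, x), y)$residuals^2)
}

#' Mean-to-excitatory synaptic current ratio (E-I balance)
#'
#' Ratio of the time-averaged total synaptic current to the time-averaged
#' excitatory synaptic current, mean(I_ex + I_inh) / mean(I_ex), computed in
#' windows of `window_ms` and averaged across windows. With the sign
#' convention I_inh < 0, the ratio approaches 0 at exact E-I balance and 1
#' for pure excitation.
#'
#' @param trace a `trace_set` covering at least one window.
#' @param window_ms averaging window (ms), default 2000.
#' @return the balance ratio.
#' @export
ei_balance_ratio <- function(trace, window_ms = 2000) {
  wlen <- round(window_ms / trace$dt_record)
  n_win <- floor(length(trace$i_ex) / wlen)
  if (n_win < 1)
    stop("trace shorter than one averaging window", call. = FALSE)
  r <- vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    mex <- mean(trace$i_ex[idx])
    if (mex == 0) stop("mean excitatory current is zero (silent network)",
                       call. = FALSE)
    mean(trace$i_ex[idx] + trace$i_inh[idx]) / mex
  }, 0)
  mean(r)
}

#' Scan excitatory coupling strength for the critical state
#'
#' For each value of `dg_ex_grid`, simulates ongoing activity (no stimulus)
#' for `sim_time_s` seconds, screens out degenerate realizations
#' (re-running with a fresh seed up to `max_retries` times), detects
#' avalanches at the simulation step, and records the power-law deviation of
#' the size distribution and the E-I current balance ratio. The deviation
#' minimum over the grid locates the critical coupling.
#'
#' @param dg_ex_grid excitatory coupling strengths to scan.
#' @param config base [network_config()] (its `dg_ex` is overridden).
#' @param bg_rate background rate (spikes/s per neuron).
#' @param sim_time_s simulated ongoing time per grid point (seconds).
#' @param seed base RNG seed.
#' @param conn optional fixed connectivity (built from `config` otherwise).
#' @param prob_floor floor for [powerlaw_deviation()].
#' @param max_retries degenerate-state re-runs per point.
#' @param warmup_ms discarded warm-up per run (ms).
#' @return An object of class `criticality_scan`: data.frame with columns
#'   `dg_ex`, `deviation`, `balance_ratio`, `mean_rate`, `n_avalanches`,
#'   `degenerate`; silent points carry `NA` deviation.
#' @export
scan_criticality <- function(dg_ex_grid, config = network_config(),
                             bg_rate = 20, sim_time_s = 120, seed = 1L,
                             conn = NULL, prob_floor = 5e-5,
                             max_retries = 3, warmup_ms = 2000) {
  if (length(dg_ex_grid) == 0) stop("empty dg_ex grid", call. = FALSE)
  if (is.null(conn)) conn <- build_network(config, seed = seed)
  rows <- lapply(seq_along(dg_ex_grid), function(i) {
    cfg <- config
    cfg$dg_ex <- dg_ex_grid[i]
    res <- NULL
    for (attempt in 0:max_retries) {
      tr <- run_trial(conn, cfg, background_spec(bg_rate), NULL,
                      duration = sim_time_s * 1000, record_traces = TRUE,
                      seed = seed + 1000L * i + attempt,
                      warmup_ms = warmup_ms)
      st <- is_degenerate_state(tr$raster, tr$trace)
      if (!st$degenerate) {
        res <- list(tr = tr, st = st)
        break
      }
    }
    if (is.null(res))
      return(data.frame(dg_ex = dg_ex_grid[i], deviation = NA_real_,
                        balance_ratio = NA_real_, mean_rate = NA_real_,
                        n_avalanches = NA_integer_, degenerate = TRUE))
    av <- detect_avalanches(res$tr$raster, dt = cfg$dt)
    dev <- if (length(av$sizes) >= 100)
      tryCatch(powerlaw_deviation(size_distribution(av), prob_floor),
               error = function(e) NA_real_) else NA_real_
    bal <- if (res$st$silent) NA_real_ else
      ei_balance_ratio(res$tr$trace)
    data.frame(dg_ex = dg_ex_grid[i], deviation = dev, balance_ratio = bal,
               mean_rate = res$st$mean_rate,
               n_avalanches = length(av$sizes), degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("criticality_scan", "data.frame")
  out
}

#' @export
print.criticality_scan <- function(x, ...) {
  cat("<criticality_scan>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  ok <- which(is.finite(x$deviation))
  if (length(ok))
    cat(sprintf("deviation minimized at dg_ex = %g\n",
                x$dg_ex[ok[which.min(x$deviation[ok])]]))
  invisible(x)
}
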