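#' Network and neuron parameters
#'
#' Builds the full parameter set of the conductance-based leaky
#' integrate-and-fire (LIF) network. All conductances are dimensionless
#' (relative to the leak conductance), potentials in mV, times in ms and
#' rates in spikes/second. Defaults are the reference parameter set: a small
#' dense network of 500 neurons, 80\% excitatory, connection density 0.16,
#' with membrane time constant 20 ms, excitatory/inhibitory synaptic decay
#' 5/10 ms, reversal potentials 0/-80 mV, threshold -50 mV and reset equal to
#' rest at -60 mV, refractory period 5 ms.
#'
#' @param n_neurons number of neurons.
#' @param frac_excitatory fraction of excitatory neurons, in (0, 1).
#' @param density connection probability for each ordered neuron pair.
#' @param dg_ex,dg_inh conductance increment per excitatory / inhibitory
#'   presynaptic spike (dimensionless).
#' @param tau_m membrane time constant (ms).
#' @param tau_ex,tau_inh synaptic decay time constants (ms).
#' @param v_rest,v_thresh,v_reset resting, threshold and reset potential (mV).
#' @param e_ex,e_inh excitatory and inhibitory reversal potentials (mV).
#' @param t_ref absolute refractory period (ms).
#' @param dt integration step (ms).
#' @param seed integer seed used when the config is the only seed source.
#' @return An object of class `network_config` (a validated list).
#' @examples
#' cfg <- network_config(dg_ex = 0.4)
#' cfg$n_neurons
#' @export
network_config <- function(n_neurons = 500L, frac_excitatory = 0.8,
                           density = 0.16, dg_ex = 0.4, dg_inh = 5.0,
                           tau_m = 20, tau_ex = 5, tau_inh = 10,
                           v_rest = -60, v_thresh = -50, v_reset = -60,
                           e_ex = 0, e_inh = -80, t_ref = 5, dt = 0.1,
                           seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              frac_excitatory = frac_excitatory, density = density,
              dg_ex = dg_ex, dg_inh = dg_inh, tau_m = tau_m, tau_ex = tau_ex,
              tau_inh = tau_inh, v_rest = v_rest, v_thresh = v_thresh,
              v_reset = v_reset, e_ex = e_ex, e_inh = e_inh, t_ref = t_ref,
              dt = dt, seed = as.integer(seed))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", what, call. = FALSE)
  }
  chk(cfg$n_neurons >= 1, "n_neurons", "must be >= 1")
  chk(cfg$frac_excitatory > 0 && cfg$frac_excitatory < 1,
      "frac_excitatory", "must be in (0, 1)")
  chk(cfg$density >= 0 && cfg$density <= 1, "density", "must be in [0, 1]")
  chk(cfg$dg_ex >= 0, "dg_ex", "must be >= 0")
  chk(cfg$dg_inh >= 0, "dg_inh", "must be >= 0")
  for (f in c("tau_m", "tau_ex", "tau_inh", "t_ref"))
    chk(cfg[[f]] > 0, f, "must be > 0")
  chk(cfg$dt > 0 && cfg$dt <= cfg$t_ref, "dt", "must satisfy 0 < dt <= t_ref")
  chk(cfg$v_rest < cfg$v_thresh, "v_rest", "must be below v_thresh")
  chk(cfg$e_inh < cfg$v_rest, "e_inh", "must be below v_rest")
  chk(cfg$e_ex > cfg$v_rest, "e_ex", "must be above v_rest")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>\n")
  cat(sprintf("  %d neurons (%.0f%% excitatory), density %.3g\n",
              x$n_neurons, 100 * x$frac_excitatory, x$density))
  cat(sprintf("  dg_ex = %.3g, dg_inh = %.3g; tau_m/ex/inh = %g/%g/%g ms\n",
              x$dg_ex, x$dg_inh, x$tau_m, x$tau_ex, x$tau_inh))
  cat(sprintf("  V rest/thresh/reset = %g/%g/%g mV; E_ex/E_inh = %g/%g mV\n",
              x$v_rest, x$v_thresh, x$v_reset, x$e_ex, x$e_inh))
  cat(sprintf("  t_ref = %g ms, dt = %g ms, seed = %d\n",
              x$t_ref, x$dt, x$seed))
  invisible(x)
}

#' Build a random directed E-I network
#'
#' Random directed graph at connection density `config$density`. The first
#' `round(frac_excitatory * n_neurons)` neurons are excitatory, the rest
#' inhibitory; identity is assigned by index block since the membrane
#' equation is homogeneous across neurons. No self-connections.
#'
#' Three samplers are provided. The default, `"regular_inh"`, draws
#' excitatory synapses as independent Bernoulli edges at probability
#' `density` and gives every neuron exactly `round(density * n_inh)`
#' inhibitory presynaptic partners, sampled uniformly without replacement.
#' `"regular"` fixes the excitatory in-degree the same way too, and
#' `"bernoulli"` makes every ordered pair an edge independently (directed
#' Erdos-Renyi). The regularity of the inhibitory in-degree matters
#' dynamically: with Bernoulli inhibitory edges the in-degree spread
#' (16 +/- 4 at the reference parameters) leaves a minority of
#' under-inhibited neurons firing through the quiet phase of the collective
#' oscillation, and the network settles into a non-oscillatory high-rate
#' asynchronous state instead of the critical quiet-burst alpha cycle.
#' Excitatory in-degree heterogeneity is harmless and adds realistic
#' rate diversity across neurons.
#'
#' @param config a [network_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param method `"regular_inh"` (default), `"regular"` or `"bernoulli"`.
#' @return An object of class `connectivity` with fields `n_neurons`,
#'   `is_excitatory` (logical per neuron), `edges` (two-column integer matrix
#'   `pre`, `post`) and `module_id` (integer per neuron, all 1 here).
#' @examples
#' conn <- build_network(network_config(n_neurons = 50), seed = 1)
#' sum(conn$is_excitatory)  # 40
#' @export
build_network <- function(config, seed = config$seed,
                          method = c("regular_inh", "regular", "bernoulli")) {
  validate_network_config(config)
  method <- match.arg(method)
  n <- config$n_neurons
  n_ex <- round(config$frac_excitatory * n)
  with_seed(seed, {
    edges <- switch(method,
      bernoulli = random_edges(n, config$density, offset_pre = 0L,
                               offset_post = 0L),
      regular = fixed_indegree_edges(n, n_ex, config$density,
                                     regular_exc = TRUE),
      regular_inh = fixed_indegree_edges(n, n_ex, config$density,
                                         regular_exc = FALSE))
  })
  conn <- list(n_neurons = n,
               is_excitatory = seq_len(n) <= n_ex,
               edges = edges,
               module_id = rep(1L, n))
  class(conn) <- "connectivity"
  conn
}

# every neuron receives exactly round(p * n_inh) inhibitory inputs,
# uniformly sampled without replacement, self excluded; excitatory inputs
# either regular the same way (regular_exc) or independent Bernoulli edges
fixed_indegree_edges <- function(n, n_ex, density, regular_exc = FALSE) {
  k_inh <- round(density * (n - n_ex))
  ipre <- if (k_inh > 0) {
    lapply(seq_len(n), function(post) {
      ipool <- setdiff(seq(n_ex + 1L, n), post)
      ipool[sample.int(length(ipool), k_inh)]
    })
  } else rep(list(integer(0)), n)
  e_inh <- cbind(pre = unlist(ipre),
                 post = rep(seq_len(n), times = lengths(ipre)))
  e_ex <- if (regular_exc) {
    k_ex <- round(density * n_ex)
    epre <- if (k_ex > 0) {
      lapply(seq_len(n), function(post) {
        epool <- setdiff(seq_len(n_ex), post)
        epool[sample.int(length(epool), k_ex)]
      })
    } else rep(list(integer(0)), n)
    cbind(pre = unlist(epre), post = rep(seq_len(n), times = lengths(epre)))
  } else {
    hit <- which(matrix(stats::runif(n_ex * n), n_ex, n) < density,
                 arr.ind = TRUE)
    hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
    cbind(pre = as.integer(hit[, 1L]), post = as.integer(hit[, 2L]))
  }
  edges <- rbind(e_ex, e_inh)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

# all directed edges between two index blocks at the given density;
# self-edges excluded when the blocks coincide
random_edges <- function(n, density, offset_pre, offset_post, n_post = n) {
  if (density <= 0)
    return(cbind(pre = integer(0), post = integer(0)))
  same <- offset_pre == offset_post
  m <- as.numeric(n) * (if (same) n_post - 1 else n_post)
  k <- stats::rbinom(1L, m, density)
  if (k == 0) return(cbind(pre = integer(0), post = integer(0)))
  # sample k distinct ordered pairs by their linear index
  idx <- sample.int(m, k)
  pre <- as.integer((idx - 1) %/% (if (same) n_post - 1 else n_post)) + 1L
  rem <- as.integer((idx - 1) %% (if (same) n_post - 1 else n_post)) + 1L
  post <- if (same) ifelse(rem >= pre, rem + 1L, rem) else rem
  ord <- order(pre, post)
  cbind(pre = pre[ord] + offset_pre, post = as.integer(post[ord]) + offset_post)
}

#' @export
print.connectivity <- function(x, ...) {
  n_mod <- length(unique(x$module_id))
  cat(sprintf("<connectivity> %d neurons (%d excitatory), %d synapses%s\n",
              x$n_neurons, sum(x$is_excitatory), nrow(x$edges),
              if (n_mod > 1) sprintf(", %d modules", n_mod) else ""))
  invisible(x)
}

#' Build a modular network of coupled dense modules
#'
#' Couples `n_modules` independent dense random networks (each a
#' [build_network()] realization of `config`) through sparser random
#' inter-module connections: every ordered pair of neurons in different
#' modules is a synapse with probability `inter_density`, which must be
#' below the within-module density.
#'
#' @param n_modules number of modules (>= 2).
#' @param config per-module [network_config()].
#' @param inter_density connection probability between modules.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `connectivity` over `n_modules * config$n_neurons` neurons with
#'   `module_id` giving each neuron's module (1-based).
#' @export
build_modular_network <- function(n_modules, config, inter_density,
                                  seed = config$seed) {
  validate_network_config(config)
  if (n_modules < 2) stop("`n_modules` must be >= 2", call. = FALSE)
  if (inter_density >= config$density)
    stop("`inter_density` must be below the within-module density ",
         config$density, call. = FALSE)
  n <- config$n_neurons
  n_ex <- round(config$frac_excitatory * n)
  with_seed(seed, {
    parts <- vector("list", n_modules * n_modules)
    for (a in seq_len(n_modules)) {
      off_a <- (a - 1L) * n
      for (b in seq_len(n_modules)) {
        off_b <- (b - 1L) * n
        e <- if (a == b) {
          within <- fixed_indegree_edges(n, n_ex, config$density)
          within + as.integer(off_a)
        } else {
          random_edges(n, inter_density, offset_pre = off_a,
                       offset_post = off_b, n_post = n)
        }
        parts[[(a - 1L) * n_modules + b]] <- e
      }
    }
  })
  edges <- do.call(rbind, parts)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  is_ex <- rep(seq_len(n) <= n_ex, n_modules)
  conn <- list(n_neurons = n_modules * n,
               is_excitatory = is_ex,
               edges = edges,
               module_id = rep(seq_len(n_modules), each = n))
  class(conn) <- "connectivity"
  conn
}

# adjacency in compressed form for the C++ core: 0-based target list plus
# per-neuron offsets
adjacency_csr <- function(conn) {
  ord <- order(conn$edges[, "pre"])
  pre <- conn$edges[ord, "pre"]
  targets <- conn$edges[ord, "post"] - 1L
  counts <- tabulate(pre, nbins = conn$n_neurons)
  offsets <- c(0L, cumsum(counts))
  list(targets = as.integer(targets), offsets = as.integer(offsets))
}

# evaluate thunk under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
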