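#' Read a simulation/analysis configuration from YAML
#'
#' The file may set any field of [network_config()], plus `background`
#' (fields of [background_spec()]) and `stimulus` (fields of
#' [stimulus_spec()], or `null` for none). Unknown keys are rejected; an
#' empty file yields the full default configuration (N = 500, density 0.16,
#' dg_ex 0.4, dg_inh 5.0, 20 Hz background, alpha-function stimulus).
#'
#' @param path YAML file path.
#' @return list with `config`, `bg`, `stim`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_net <- names(formals(network_config))
  net_keys <- setdiff(names(raw), c("background", "stimulus"))
  bad <- setdiff(net_keys, known_net)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  config <- do.call(network_config, raw[net_keys])
  bgl <- raw$background
  bad <- setdiff(names(bgl), names(formals(background_spec)))
  if (length(bad))
    stop("unknown background key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bg <- do.call(background_spec, if (is.null(bgl)) list() else bgl)
  stim <- if (!is.null(raw$stimulus) && identical(raw$stimulus, "none")) {
    NULL
  } else {
    stl <- raw$stimulus
    bad <- setdiff(names(stl), names(formals(stimulus_spec)))
    if (length(bad))
      stop("unknown stimulus key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(stimulus_spec, if (is.null(stl)) list() else stl)
  }
  list(config = config, bg = bg, stim = stim)
}

#' Write a configuration to YAML
#'
#' Inverse of [read_config()]; round-trips exactly.
#'
#' @param config a [network_config()].
#' @param path output file.
#' @param bg optional [background_spec()].
#' @param stim optional [stimulus_spec()]; written as `"none"` when `NULL`
#'   and `write_stim = TRUE`.
#' @param write_stim include a stimulus entry even when `stim` is `NULL`.
#' @export
write_config <- function(config, path, bg = NULL, stim = NULL,
                         write_stim = FALSE) {
  out <- unclass(config)
  if (!is.null(bg)) out$background <- unclass(bg)
  if (!is.null(stim)) out$stimulus <- unclass(stim)
  else if (write_stim) out$stimulus <- "none"
  yaml::write_yaml(out, path)
}

#' Write / read a spike raster as TSV
#'
#' Columns `trial`, `neuron`, `time_ms`; header lines (`#`) carry the
#' raster extent and neuron count.
#'
#' @param raster a `spike_raster` or `trial_ensemble`.
#' @param path file path.
#' @export
write_raster <- function(raster, path) {
  rl <- as_raster_list(raster)
  r1 <- rl[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d t_start=%g t_end=%g",
                     r1$n_neurons, r1$t_start, r1$t_end), con)
  writeLines("trial\tneuron\ttime_ms", con)
  for (r in rl) {
    if (length(r$time))
      writeLines(sprintf("%d\t%d\t%.4f", r$trial_id, r$neuron, r$time), con)
  }
}

#' @rdname write_raster
#' @return `read_raster()` returns a list of `spike_raster`s (one per trial).
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1)
  field <- function(key)
    as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", hdr))
  n_neurons <- as.integer(field("n_neurons"))
  t_start <- field("t_start")
  t_end <- field("t_end")
  df <- utils::read.delim(path, skip = 1)
  lapply(split(df, df$trial), function(d)
    new_spike_raster(d$neuron, d$time_ms, n_neurons, t_start, t_end,
                     trial_id = d$trial[1]))
}

#' Write / read connectivity as an edge-list TSV
#'
#' Columns `pre`, `post`; header lines carry the neuron count, the
#' excitatory labels and module ids.
#'
#' @param conn a `connectivity`.
#' @param path file path.
#' @export
write_connectivity <- function(conn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d", conn$n_neurons), con)
  writeLines(paste0("# excitatory=",
                    paste(as.integer(conn$is_excitatory), collapse = "")), con)
  writeLines(paste0("# module=", paste(conn$module_id, collapse = ",")), con)
  writeLines("pre\tpost", con)
  writeLines(sprintf("%d\t%d", conn$edges[, "pre"], conn$edges[, "post"]), con)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  hdr <- readLines(path, n = 3)
  n <- as.integer(sub(".*n_neurons=", "", hdr[1]))
  exc <- as.integer(strsplit(sub(".*excitatory=", "", hdr[2]), "")[[1]]) == 1
  mod <- as.integer(strsplit(sub(".*module=", "", hdr[3]), ",")[[1]])
  df <- utils::read.delim(path, skip = 3)
  structure(list(n_neurons = n, is_excitatory = exc,
                 edges = cbind(pre = as.integer(df$pre),
                               post = as.integer(df$post)),
                 module_id = mod),
            class = "connectivity")
}

#' Run an end-to-end analysis pipeline and write its outputs
#'
#' Drives the full pipeline for one family of results and writes CSV tables
#' plus a JSON run manifest (config snapshot, seeds, output inventory with
#' checksums) into `out_dir`:
#' \describe{
#'   \item{`ongoing`}{long ongoing simulation: LFP trace, power spectrum,
#'     avalanche sizes and truncated power-law fit.}
#'   \item{`response`}{stimulus-aligned ensembles for the critical,
#'     subcritical and supercritical couplings (dg_ex 0.4, 0.25, 1.0 at
#'     dg_inh 5.0): ERP, PSTH and alpha-power course per regime.}
#'   \item{`scan`}{criticality scan over dg_ex: deviation and balance ratio
#'     per grid point, with the argmin reported in the manifest.}
#'   \item{`variability`}{CV and FF time courses from a response ensemble.}
#' }
#'
#' @param which one of `"ongoing"`, `"response"`, `"scan"`, `"variability"`.
#' @param config a [network_config()].
#' @param out_dir output directory (created if needed).
#' @param seed base RNG seed.
#' @param bg a [background_spec()].
#' @param n_trials trials per ensemble (response/variability).
#' @param sim_time_s ongoing simulated seconds (ongoing/scan).
#' @param dg_ex_grid scan grid.
#' @return the run manifest (invisibly), also written as `manifest.json`.
#' @export
run_figure_driver <- function(which = c("ongoing", "response", "scan",
                                        "variability"),
                              config = network_config(), out_dir,
                              seed = 1L, bg = background_spec(20),
                              n_trials = 200, sim_time_s = 120,
                              dg_ex_grid = c(0.2, 0.25, 0.3, 0.4, 0.5,
                                             0.7, 1.0)) {
  which <- match.arg(which)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  info <- list()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  conn <- build_network(config, seed = seed)

  if (which == "ongoing") {
    tr <- run_trial(conn, config, bg, NULL, duration = sim_time_s * 1000,
                    seed = seed)
    put(data.frame(time = tr$trace$t_start +
                     (seq_along(tr$trace$lfp) - 1) * tr$trace$dt_record,
                   i_ex = tr$trace$i_ex, i_inh = tr$trace$i_inh,
                   lfp = tr$trace$lfp), "lfp.csv")
    sp <- power_spectrum(tr$trace$lfp, fs = 1000 / tr$trace$dt_record)
    put(as.data.frame(sp), "spectrum.csv")
    av <- detect_avalanches(tr$raster, dt = config$dt)
    put(data.frame(size = av$sizes, duration = av$durations),
        "avalanches.csv")
    fit <- fit_truncated_powerlaw(av$sizes, seed = seed)
    info$powerlaw_fit <- unclass(fit)
    info$spectral_peak <- spectral_peak(sp, 2, 50)
  } else if (which == "scan") {
    sc <- scan_criticality(dg_ex_grid, config, bg_rate = bg$rate,
                           sim_time_s = sim_time_s, seed = seed,
                           conn = conn)
    put(as.data.frame(sc), "scan.csv")
    ok <- which(is.finite(sc$deviation))
    info$deviation_argmin <- sc$dg_ex[ok[which.min(sc$deviation[ok])]]
  } else if (which == "response") {
    for (dg in c(0.4, 0.25, 1.0)) {
      cfg <- config; cfg$dg_ex <- dg
      ens <- run_ensemble(n_trials, conn, cfg, bg, stimulus_spec(),
                          t_pre = 1000, t_post = 1000, base_seed = seed)
      tag <- sprintf("dgex%s", sub("[.]", "p", format(dg)))
      put(compute_erp(ens), sprintf("erp_%s.csv", tag))
      put(compute_psth(ens), sprintf("psth_%s.csv", tag))
      tfr <- morlet_tfr(ensemble_lfp_matrix(ens), fs = 1000, freqs = 2:30,
                        times = compute_erp(ens)$time)
      put(band_power_course(tfr), sprintf("alpha_power_%s.csv", tag))
    }
  } else { # variability
    ens <- run_ensemble(n_trials, conn, config, bg, stimulus_spec(),
                        t_pre = 1000, t_post = 1000, base_seed = seed)
    cv <- windowed_cv(ens)
    ff <- windowed_ff(ens)
    put(merge(cv, ff[, c("time", "ff", "mean_count")], by = "time"),
        "variability.csv")
  }

  manifest <- list(
    which = which, seed = seed,
    package_version = as.character(utils::packageVersion("critnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config), background = unclass(bg),
    n_trials = n_trials, sim_time_s = sim_time_s,
    info = info,
    outputs = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
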