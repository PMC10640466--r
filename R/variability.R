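#' Inter-spike intervals from a raster
#'
#' Consecutive spike-time differences per neuron within `[t_lo, t_hi)`.
#' `pooled = TRUE` concatenates the per-neuron ISIs; `multiunit = TRUE`
#' instead merges all spikes into one train first and differences that
#' (emulating a multiunit electrode). Neurons with fewer than two spikes
#' contribute nothing.
#'
#' @param raster a `spike_raster`.
#' @param t_lo,t_hi window (ms); defaults to the raster extent.
#' @param pooled concatenate ISIs across neurons (default TRUE).
#' @param multiunit difference the merged spike train instead.
#' @return numeric vector of ISIs (ms); a list per neuron when
#'   `pooled = FALSE`.
#' @examples
#' r <- critnet:::new_spike_raster(rep(1, 4), c(0, 10, 30, 60), 1, 0, 100)
#' isi_list(r)  # 10 20 30
#' @export
isi_list <- function(raster, t_lo = raster$t_start, t_hi = raster$t_end,
                     pooled = TRUE, multiunit = FALSE) {
  if (t_lo >= t_hi) stop("`t_lo` must be below `t_hi`", call. = FALSE)
  keep <- raster$time >= t_lo & raster$time < t_hi
  tt <- raster$time[keep]
  nn <- raster$neuron[keep]
  if (multiunit) return(diff(sort(tt)))
  isis <- lapply(split(tt, nn), function(x) diff(sort(x)))
  isis <- isis[lengths(isis) > 0]
  if (pooled) unlist(isis, use.names = FALSE) else isis
}

#' Coefficient of variation of inter-spike intervals
#'
#' Sample standard deviation (n-1 denominator) of the ISIs divided by their
#' mean: 1 for a Poisson process, 0 for a periodic one.
#'
#' @param isis numeric ISIs.
#' @return CV, or `NA` when fewer than 2 ISIs are available.
#' @examples
#' isi_cv(c(10, 20, 30))  # 0.5
#' @export
isi_cv <- function(isis) {
  if (length(isis) < 2) return(NA_real_)
  stats::sd(isis) / mean(isis)
}

#' Sliding-window CV time course
#'
#' CV of the multiunit-merged ISIs inside each sliding window. With
#' `per_trial = FALSE` (default) the ISIs of all trials are pooled per
#' window and one CV is computed; with `per_trial = TRUE` a CV is computed
#' per trial per window and averaged across trials, the estimate a
#' trial-averaged variability figure shows. Windows with fewer than
#' `min_isis` intervals are reported as `NA`, not zero. A per-neuron
#' (pooled rather than merged) mode is available via `multiunit = FALSE`.
#'
#' @param rasters a `spike_raster`, a list of them, or a `trial_ensemble`.
#' @param window_ms window length (ms), default 100.
#' @param step_ms window step (ms), default 10.
#' @param neurons optional neuron subset.
#' @param multiunit merge spikes within each window (default TRUE).
#' @param min_isis minimum intervals per window (default 5; per trial when
#'   `per_trial = TRUE`, where it defaults to 2).
#' @param per_trial average per-trial CVs instead of pooling ISIs.
#' @return An object of class `variability_course`: data.frame with columns
#'   `time` (window centre, ms), `cv`, `n_isis`.
#' @export
windowed_cv <- function(rasters, window_ms = 100, step_ms = 10,
                        neurons = NULL, multiunit = TRUE, min_isis = NULL,
                        per_trial = FALSE) {
  if (is.null(min_isis)) min_isis <- if (per_trial) 2 else 5
  if (window_ms <= 0) stop("`window_ms` must be > 0", call. = FALSE)
  rl <- as_raster_list(rasters)
  r1 <- rl[[1]]
  centers <- seq(r1$t_start + window_ms / 2, r1$t_end - window_ms / 2,
                 by = step_ms)
  # precompute, per trial, the candidate intervals (time of the later spike,
  # interval length); a window's ISIs are those fully inside it
  prep <- lapply(rl, function(r) {
    keep <- if (is.null(neurons)) TRUE else r$neuron %in% neurons
    tt <- r$time[keep]
    if (multiunit) {
      tt <- sort(tt)
      list(t_hi = tt[-1], isi = diff(tt))
    } else {
      nn <- r$neuron[keep]
      ord <- order(nn, tt)
      tt <- tt[ord]; nn <- nn[ord]
      same <- diff(nn) == 0
      list(t_hi = tt[-1][same], isi = diff(tt)[same])
    }
  })
  if (per_trial) {
    cvs <- vapply(prep, function(p) {
      ord <- order(p$t_hi)
      t_hi <- p$t_hi[ord]; isi <- p$isi[ord]; t_lo <- t_hi - isi
      vapply(centers, function(cc) {
        i0 <- findInterval(cc - window_ms / 2, t_hi, left.open = TRUE) + 1L
        i1 <- findInterval(cc + window_ms / 2, t_hi, left.open = TRUE)
        k <- if (i0 > i1) integer(0) else i0:i1
        k <- k[t_lo[k] >= cc - window_ms / 2]
        if (length(k) >= max(2, min_isis)) isi_cv(isi[k]) else NA_real_
      }, 0)
    }, numeric(length(centers)))
    cvs <- matrix(cvs, nrow = length(centers))
    out <- data.frame(time = centers,
                      cv = rowMeans(cvs, na.rm = TRUE),
                      n_isis = as.integer(rowSums(!is.na(cvs))))
    out$cv[out$n_isis == 0] <- NA_real_
  } else {
    t_hi <- unlist(lapply(prep, `[[`, "t_hi"), use.names = FALSE)
    isi <- unlist(lapply(prep, `[[`, "isi"), use.names = FALSE)
    ord <- order(t_hi)
    t_hi <- t_hi[ord]; isi <- isi[ord]
    t_lo <- t_hi - isi
    stats <- vapply(centers, function(cc) {
      i0 <- findInterval(cc - window_ms / 2, t_hi, left.open = TRUE) + 1L
      i1 <- findInterval(cc + window_ms / 2, t_hi, left.open = TRUE)
      k <- if (i0 > i1) integer(0) else i0:i1
      k <- k[t_lo[k] >= cc - window_ms / 2]
      c(n = length(k),
        cv = if (length(k) >= max(2, min_isis)) isi_cv(isi[k]) else NA_real_)
    }, c(n = 0, cv = 0))
    out <- data.frame(time = centers, cv = stats["cv", ],
                      n_isis = as.integer(stats["n", ]))
  }
  class(out) <- c("variability_course", "data.frame")
  out
}

#' Sliding-window Fano factor time course
#'
#' Per window: variance across trials of the multiunit spike count divided
#' by the mean count (sample variance, n-1): 1 for a homogeneous Poisson
#' process, 0 for identical counts. Windows with zero mean count are `NA`.
#'
#' @param ensemble a `trial_ensemble` or list of >= 2 `spike_raster`s.
#' @param window_ms window length (ms), default 100.
#' @param step_ms window step (ms), default 10.
#' @param neurons optional neuron subset (multiunit emulation).
#' @return An object of class `variability_course`: data.frame with columns
#'   `time`, `ff`, `mean_count`.
#' @export
windowed_ff <- function(ensemble, window_ms = 100, step_ms = 10,
                        neurons = NULL) {
  rl <- as_raster_list(ensemble)
  if (length(rl) < 2) stop("need >= 2 trials for the Fano factor",
                           call. = FALSE)
  r1 <- rl[[1]]
  centers <- seq(r1$t_start + window_ms / 2, r1$t_end - window_ms / 2,
                 by = step_ms)
  counts <- vapply(rl, function(r) {
    tt <- r$time
    if (!is.null(neurons)) tt <- tt[r$neuron %in% neurons]
    tt <- sort(tt)
    hi <- findInterval(centers + window_ms / 2, tt, left.open = TRUE)
    lo <- findInterval(centers - window_ms / 2, tt, left.open = TRUE)
    hi - lo
  }, numeric(length(centers)))
  counts <- matrix(counts, nrow = length(centers))
  mu <- rowMeans(counts)
  va <- apply(counts, 1, stats::var)
  ff <- ifelse(mu > 0, va / mu, NA_real_)
  out <- data.frame(time = centers, ff = ff, mean_count = mu)
  class(out) <- c("variability_course", "data.frame")
  out
}

as_raster_list <- function(x) {
  if (inherits(x, "trial_ensemble")) return(x$rasters)
  if (inherits(x, "spike_raster")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "spike_raster"))) return(x)
  stop("expected a spike_raster, a list of them, or a trial_ensemble",
       call. = FALSE)
}
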