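#' Averaged-periodogram (Welch) power spectrum
#'
#' Splits the series into overlapping segments, removes each segment's mean,
#' applies a Hann taper and averages the periodograms. Defaults: 2-s
#' segments, 50% overlap. Power is normalized so that the spectrum sums
#' (times the frequency step) to approximately the series variance.
#'
#' @param lfp numeric time series.
#' @param fs sampling rate (Hz).
#' @param segment_s segment length (seconds).
#' @param overlap_frac fractional segment overlap in [0, 1).
#' @return An object of class `spectrum_est`: data.frame with columns
#'   `frequency` (Hz, excluding DC) and `power`, plus attributes
#'   `segment_s`, `overlap_frac`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1e-3))
#' sp <- power_spectrum(x, fs = 1000)
#' sp$frequency[which.max(sp$power)]  # 10
#' @export
power_spectrum <- function(lfp, fs, segment_s = 2, overlap_frac = 0.5) {
  nseg <- round(segment_s * fs)
  step <- max(1, round(nseg * (1 - overlap_frac)))
  if (length(lfp) < nseg + step)
    stop("series too short: need at least 2 segments", call. = FALSE)
  starts <- seq(1, length(lfp) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann taper
  u <- sum(w^2)
  acc <- numeric(nseg %/% 2)
  for (s0 in starts) {
    seg <- lfp[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    acc <- acc + p[2:(nseg %/% 2 + 1)]
  }
  pw <- 2 * acc / length(starts)        # one-sided
  freq <- (seq_len(nseg %/% 2)) * fs / nseg
  out <- data.frame(frequency = freq, power = pw)
  attr(out, "segment_s") <- segment_s
  attr(out, "overlap_frac") <- overlap_frac
  class(out) <- c("spectrum_est", "data.frame")
  out
}

#' Spectral peak within a band
#'
#' Smooths the power with a 3-point moving average and returns the frequency
#' and height of the maximum inside `[band_lo, band_hi]`.
#'
#' @param spec a `spectrum_est` (or data.frame with `frequency`, `power`).
#' @param band_lo,band_hi band edges (Hz).
#' @return list with `peak_freq` (Hz) and `peak_height`.
#' @export
spectral_peak <- function(spec, band_lo, band_hi) {
  sm <- stats::filter(spec$power, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- spec$power[is.na(sm)]
  keep <- spec$frequency >= band_lo & spec$frequency <= band_hi
  if (!any(keep)) stop("empty frequency band", call. = FALSE)
  i <- which(keep)[which.max(sm[keep])]
  list(peak_freq = spec$frequency[i], peak_height = as.numeric(sm[i]))
}

# complex Morlet wavelet transform of one signal at the given frequencies,
# by FFT convolution; returns a length(signal) x length(freqs) modulus matrix
morlet_modulus <- function(x, fs, freqs, n_cycles) {
  nx <- length(x)
  # longest wavelet support determines padding
  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- ceiling(3 * max(sigma_t) * fs)
  nfft <- stats::nextn(nx + 2 * half, 2)
  fx <- stats::fft(c(x, rep(0, nfft - nx)))
  out <- matrix(0, nx, length(freqs))
  tt <- (seq_len(nfft) - 1) / fs
  tt <- ifelse(tt > nfft / fs / 2, tt - nfft / fs, tt)  # centered time axis
  for (j in seq_along(freqs)) {
    st <- sigma_t[j]
    w <- exp(-tt^2 / (2 * st^2)) * exp(2i * pi * freqs[j] * tt)
    w <- w / sum(Mod(w))                 # unit l1 norm: tone -> amplitude/2
    conv <- stats::fft(fx * Conj(stats::fft(w)), inverse = TRUE) / nfft
    out[, j] <- Mod(conv[seq_len(nx)])
  }
  out
}

#' Morlet wavelet time-frequency map
#'
#' Convolves each trial with complex Morlet wavelets (fixed number of cycles
#' per frequency) and averages the modulus across trials, the standard
#' estimate of induced (non-phase-locked plus phase-locked) power used for
#' event-related desynchronization analysis.
#'
#' @param signals matrix of trials (rows = time samples, cols = trials) or a
#'   numeric vector for a single trial.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz), all below fs/2.
#' @param n_cycles wavelet cycles (default 6, fixed across frequencies).
#' @param times optional time axis (ms) for the rows.
#' @return An object of class `tfr_map`: list with `times` (ms),
#'   `frequencies` (Hz), `magnitude` (time x frequency matrix, trial-averaged
#'   modulus) and `edge` (logical time x frequency matrix flagging samples
#'   within one wavelet support, 3 Gaussian SDs, of either end).
#' @export
morlet_tfr <- function(signals, fs, freqs = 2:50, n_cycles = 6,
                       times = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("analysis frequencies must lie in (0, fs/2)", call. = FALSE)
  nx <- nrow(signals)
  acc <- matrix(0, nx, length(freqs))
  for (k in seq_len(ncol(signals)))
    acc <- acc + morlet_modulus(signals[, k], fs, freqs, n_cycles)
  acc <- acc / ncol(signals)
  if (is.null(times)) times <- (seq_len(nx) - 1) / fs * 1000
  half_ms <- 3 * n_cycles / (2 * pi * freqs) * 1000
  edge <- vapply(half_ms, function(h)
    times < times[1] + h | times > times[nx] - h, logical(nx))
  structure(list(times = times, frequencies = freqs, magnitude = acc,
                 edge = edge, n_trials = ncol(signals)),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf(
    "<tfr_map> %d x %d (time x frequency), %d trial(s), f in [%g, %g] Hz\n",
    length(x$times), length(x$frequencies), x$n_trials,
    min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Band-averaged power time course
#'
#' Mean wavelet magnitude across a frequency band per time sample; with the
#' default 8-12 Hz band this is the alpha-power course used to quantify
#' event-related desynchronization.
#'
#' @param tfr a `tfr_map`.
#' @param band_lo,band_hi band edges (Hz), default 8-12.
#' @param baseline optional `c(t0, t1)` (ms): subtractively normalize by the
#'   mean over that window.
#' @return data.frame with `time` (ms) and `power`.
#' @export
band_power_course <- function(tfr, band_lo = 8, band_hi = 12,
                              baseline = NULL) {
  keep <- tfr$frequencies >= band_lo & tfr$frequencies <= band_hi
  if (!any(keep)) stop("empty frequency band", call. = FALSE)
  p <- rowMeans(tfr$magnitude[, keep, drop = FALSE])
  if (!is.null(baseline)) {
    bl <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
    p <- p - mean(p[bl])
  }
  data.frame(time = tfr$times, power = p)
}

ensemble_lfp_matrix <- function(ensemble) {
  lens <- vapply(ensemble$traces, function(t) length(t$lfp), 0L)
  if (length(unique(lens)) != 1 ||
      length(unique(vapply(ensemble$traces, function(t) t$t_start, 0))) != 1)
    stop("misaligned trials: traces differ in length or start time",
         call. = FALSE)
  vapply(ensemble$traces, function(t) t$lfp, numeric(lens[1]))
}

#' Trial-averaged event-related potential of the LFP proxy
#'
#' Pointwise mean of the stimulus-aligned LFP traces across trials,
#' optionally baseline-corrected by the pre-stimulus mean.
#'
#' @param ensemble a `trial_ensemble` with recorded traces.
#' @param baseline optional `c(t0, t1)` (ms) subtractive baseline window.
#' @return data.frame with `time` (ms, stimulus onset at 0) and `erp`.
#' @export
compute_erp <- function(ensemble, baseline = NULL) {
  m <- ensemble_lfp_matrix(ensemble)
  tr1 <- ensemble$traces[[1]]
  time <- tr1$t_start + (seq_len(nrow(m)) - 1) * tr1$dt_record
  erp <- rowMeans(m)
  if (!is.null(baseline))
    erp <- erp - mean(erp[time >= baseline[1] & time <= baseline[2]])
  data.frame(time = time, erp = erp)
}

#' Peristimulus time histogram from a multiunit subset
#'
#' Emulates a multiunit recording: spike counts of a fixed random subset of
#' neurons (chosen once per ensemble from the ensemble seed) in a sliding
#' window, averaged across trials and converted to spikes/second per neuron.
#'
#' @param ensemble a `trial_ensemble`.
#' @param window_ms sliding-window length (ms), default 5.
#' @param subset_size number of multiunit neurons (default 20).
#' @param step_ms window step (ms), default 1.
#' @param neurons optional explicit neuron subset (overrides random choice).
#' @return data.frame with `time` (window centre, ms) and `rate`
#'   (spikes/s per neuron).
#' @export
compute_psth <- function(ensemble, window_ms = 5, subset_size = 20,
                         step_ms = 1, neurons = NULL) {
  if (window_ms <= 0) stop("`window_ms` must be > 0", call. = FALSE)
  n_total <- ensemble$rasters[[1]]$n_neurons
  if (is.null(neurons)) {
    if (subset_size > n_total)
      stop("subset larger than the population", call. = FALSE)
    neurons <- with_seed(ensemble$seeds[1],
                         sample.int(n_total, subset_size))
  }
  r1 <- ensemble$rasters[[1]]
  centers <- seq(r1$t_start + window_ms / 2, r1$t_end - window_ms / 2,
                 by = step_ms)
  acc <- numeric(length(centers))
  for (r in ensemble$rasters) {
    tt <- r$time[r$neuron %in% neurons]
    if (length(tt) == 0) next
    # count spikes in [c - w/2, c + w/2) per window via sorted times
    tt <- sort(tt)
    lo <- findInterval(centers - window_ms / 2, tt, left.open = TRUE)
    hi <- findInterval(centers + window_ms / 2, tt, left.open = TRUE)
    acc <- acc + (hi - lo)
  }
  rate <- acc / length(ensemble$rasters) / length(neurons) /
    (window_ms / 1000)
  data.frame(time = centers, rate = rate)
}
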