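# Electrophysiology: zero-phase filtering, threshold spike detection,
# Gaussian-kernel rate estimation, multitaper spectrograms, EMG power and
# laminar current source density.

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`), so
#' the net filter has zero group delay.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges (Hz), `0 < lo < hi < fs/2`.
#' @param order Butterworth order of each pass.
#' @return Filtered trace.
#' @export
bandpass <- function(x, fs, lo, hi, order = 4) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Threshold-based multiunit spike detection
#'
#' Spikes are samples whose absolute deviation from the trace mean exceeds
#' `threshold_sd` standard deviations; after a detection, further crossings
#' within the refractory period are discarded (the first crossing of a
#' violating pair is kept).  The caller is expected to supply a trace
#' band-passed to the multiunit band.
#'
#' @param x Band-passed voltage trace.
#' @param fs Sampling rate (Hz).
#' @param threshold_sd Threshold multiplier (default 4).
#' @param refractory Minimum inter-spike interval (s, default 1 ms).
#' @param method Spread estimator: `"sd"` (default) or `"mad"` (robust).
#' @return A `spike_train` object: list with `times` (s, sorted), `n`,
#'   `threshold` and the parameters used.
#' @export
detect_spikes <- function(x, fs, threshold_sd = 4, refractory = 0.001,
                          method = c("sd", "mad")) {
  method <- match.arg(method)
  m <- mean(x)
  s <- if (method == "sd") stats::sd(x) else stats::mad(x)
  if (!is.finite(s) || s == 0) stop("trace has zero dispersion")
  thr <- threshold_sd * s
  cand <- which(abs(x - m) > thr)
  times <- (cand - 1L) / fs
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  structure(list(times = times[keep], n = sum(keep), threshold = thr,
                 threshold_sd = threshold_sd, refractory = refractory,
                 method = method),
            class = "spike_train")
}

#' Smoothed firing-rate estimate from spike times
#'
#' Convolves the binarized spike train with a unit-area Gaussian kernel
#' (default sd 100 ms), so the trace has units of Hz and integrates to the
#' spike count (edge spikes lose the kernel mass falling outside the trace).
#'
#' @param times Spike times (s) or a `spike_train`.
#' @param duration Output duration (s).
#' @param sigma Kernel standard deviation (s).
#' @param fs_out Output sampling rate (Hz).
#' @return List with `time`, `rate` (Hz) and `fs`.
#' @export
spike_rate <- function(times, duration, sigma = 0.1, fs_out = 100) {
  if (inherits(times, "spike_train")) times <- times$times
  if (sigma <= 0) stop("sigma must be > 0")
  n <- round(duration * fs_out)
  counts <- numeric(n)
  if (length(times)) {
    idx <- floor(times * fs_out) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    tab <- tabulate(idx, nbins = n)
    counts <- tab
  }
  rate <- conv_same(counts * fs_out, gauss_kernel(fs_out, sigma))
  list(time = (seq_len(n) - 1L) / fs_out, rate = rate, fs = fs_out)
}

#' Sliding-window multitaper spectrogram
#'
#' @param x Trace (e.g. LFP).
#' @param fs Sampling rate (Hz).
#' @param window Window length (s, default 5).
#' @param step Step between windows (s, default 0.5).
#' @param nw,k Multitaper parameters.
#' @return List with `time` (window centers, s), `freq` (Hz) and `power`
#'   (freq x time matrix).
#' @export
mt_spectrogram <- function(x, fs, window = 5, step = 0.5, nw = 3, k = 5) {
  nwin <- round(window * fs)
  nstep <- round(step * fs)
  if (length(x) < nwin) stop("trace shorter than one window")
  starts <- seq.int(1L, length(x) - nwin + 1L, by = nstep)
  tapers <- dpss_tapers(nwin, nw, k)
  spec <- vapply(starts, function(i) {
    multitaper_psd(x[i:(i + nwin - 1L)], fs, nw, k, tapers = tapers)$power
  }, numeric(nwin %/% 2L))
  freq <- (1:(nwin %/% 2L)) * fs / nwin
  list(time = (starts - 1L) / fs + window / 2, freq = freq, power = spec)
}

#' Normalize a spectrogram against a baseline period
#'
#' Per-frequency percentage change relative to the mean power during the
#' baseline interval (at least 2 minutes of rest).
#'
#' @param spec A [mt_spectrogram()] result.
#' @param baseline_interval `c(start, end)` in seconds.
#' @param min_baseline Minimum baseline length (s).
#' @return `spec` with `power` replaced by percent change.
#' @export
normalize_spectrogram <- function(spec, baseline_interval,
                                  min_baseline = 120) {
  if (diff(baseline_interval) < min_baseline)
    stop(sprintf("baseline must span at least %g s", min_baseline))
  inb <- spec$time >= baseline_interval[1] & spec$time < baseline_interval[2]
  if (!any(inb)) stop("no spectrogram windows inside the baseline interval")
  base <- rowMeans(spec$power[, inb, drop = FALSE])
  spec$power <- 100 * sweep(sweep(spec$power, 1L, base, "-"), 1L, base, "/")
  spec$baseline_interval <- baseline_interval
  spec
}

#' EMG power trace
#'
#' The nuchal EMG processing chain: band-pass (default 300 Hz - 5 kHz,
#' clamped below Nyquist with a warning when the sampling rate cannot carry
#' the full band), rectify, square, and smooth with a Gaussian kernel
#' (default sd 50 ms).
#'
#' @param x Raw EMG trace.
#' @param fs Sampling rate (Hz).
#' @param band Band edges (Hz).
#' @param smooth_sd Gaussian kernel sd (s).
#' @return Nonnegative power trace at `fs`.
#' @export
emg_power <- function(x, fs, band = c(300, 5000), smooth_sd = 0.05) {
  hi <- band[2]
  if (hi >= fs / 2) {
    hi <- 0.999 * fs / 2
    warning(sprintf(
      "EMG band clamped to %.0f-%.0f Hz (fs = %g Hz cannot carry %g Hz)",
      band[1], hi, fs, band[2]))
  }
  filt <- bandpass(x, fs, band[1], hi)
  gauss_smooth(abs(filt)^2, fs, smooth_sd)
}

#' Band-limited LFP power trace
#'
#' Zero-phase band-pass, square, Gaussian smoothing; used to build the
#' per-bin delta/theta/gamma features for arousal scoring.  Bands that are
#' narrow relative to the sampling rate (where a high-order band-pass is
#' numerically unstable) are decimated first by zero-phase spectral
#' truncation, filtered at the reduced rate, and the smoothed power is
#' interpolated back onto the original grid.
#'
#' @param x Raw LFP trace.
#' @param fs Sampling rate (Hz).
#' @param band Band edges (Hz), e.g. `c(1, 4)` for delta.
#' @param smooth_sd Gaussian kernel sd (s).
#' @return Nonnegative power trace at `fs`.
#' @export
band_power_trace <- function(x, fs, band, smooth_sd = 0.2) {
  m <- max(1L, floor(fs / max(10 * band[2], 50)))
  if (m > 1L) {
    xd <- decimate_fft(x, m)
    fsd <- fs / m
    p <- gauss_smooth(bandpass(xd, fsd, band[1], band[2])^2, fsd, smooth_sd)
    td <- (seq_along(p) - 1L) / fsd
    tt <- (seq_along(x) - 1L) / fs
    p <- stats::approx(td, p, xout = tt, rule = 2)$y
  } else {
    p <- gauss_smooth(bandpass(x, fs, band[1], band[2])^2, fs, smooth_sd)
  }
  pmax(p, 0)
}

# Zero-phase decimation by integer factor m: brick-wall low-pass by
# truncating the spectrum, then exact subsampling (trailing samples beyond a
# multiple of m are dropped).
decimate_fft <- function(x, m) {
  n <- (length(x) %/% m) * m
  x <- x[seq_len(n)]
  nd <- n %/% m
  X <- stats::fft(x)
  half <- nd %/% 2L
  Xb <- complex(length.out = nd)
  Xb[1] <- X[1]
  Xb[2:(half + 1L)] <- X[2:(half + 1L)]
  Xb[(half + 1L):nd][-1L] <- Conj(rev(X[2:(nd - half)]))
  if (nd %% 2L == 0L) Xb[half + 1L] <- 0  # drop the new Nyquist bin
  Re(stats::fft(Xb, inverse = TRUE)) / n
}

#' Current source density of a laminar LFP array
#'
#' Second spatial derivative across uniformly spaced channels, in the
#' sink-positive convention: a localized negative-potential trough yields a
#' positive CSD value at its channel.  The two edge channels have no CSD.
#'
#' @param lfp Channels x time numeric matrix (channel 1 most superficial).
#' @param spacing Inter-channel spacing (same length unit throughout).
#' @return (channels - 2) x time CSD matrix; row `i` corresponds to input
#'   channel `i + 1`.
#' @export
csd <- function(lfp, spacing = 1) {
  if (!is.matrix(lfp) || nrow(lfp) < 3L)
    stop("need at least 3 channels for CSD")
  nch <- nrow(lfp)
  (lfp[1:(nch - 2L), , drop = FALSE] -
     2 * lfp[2:(nch - 1L), , drop = FALSE] +
     lfp[3:nch, , drop = FALSE]) / spacing^2
}

#' Identify the layer-4 channel from stimulus-evoked CSD sinks
#'
#' Averages the CSD across stimuli and finds, within the post-stimulus
#' window, the channel carrying the earliest of the largest sinks (channels
#' within `amp_tol` of the global maximum sink are candidates; the earliest
#' peak wins).
#'
#' @param csd_mat CSD matrix from [csd()] (rows map to channels 2..n-1).
#' @param fs Sampling rate (Hz).
#' @param stim_onsets Stimulus onset times (s).
#' @param window Post-stimulus search window (s).
#' @param amp_tol Fraction of the maximum sink that still counts as "largest".
#' @return List with `channel` (index into the original array), `latency`
#'   (s) and the per-channel sink table.
#' @export
layer4_channel <- function(csd_mat, fs, stim_onsets, window = c(0, 0.05),
                           amp_tol = 0.8) {
  nt <- ncol(csd_mat)
  rel <- win_idx(fs, window[1], window[2], nt)
  acc <- matrix(0, nrow(csd_mat), length(rel))
  nused <- 0L
  for (on in stim_onsets) {
    i0 <- round(on * fs)
    idx <- i0 + rel
    if (idx[1] < 1L || idx[length(idx)] > nt) next
    acc <- acc + csd_mat[, idx, drop = FALSE]
    nused <- nused + 1L
  }
  if (nused == 0L) stop("no stimulus with full window coverage")
  acc <- acc / nused
  peak <- apply(acc, 1L, max)
  lat <- (apply(acc, 1L, which.max) + rel[1] - 2L) / fs
  cand <- which(peak >= amp_tol * max(peak))
  ch <- cand[which.min(lat[cand])]
  list(channel = ch + 1L, latency = lat[ch],
       sinks = data.frame(channel = seq_len(nrow(acc)) + 1L,
                          peak_sink = peak, latency = lat))
}

#' Stimulus-evoked firing-rate summaries
#'
#' Mean rate in the early (0-100 ms) and steady-state (200-500 ms)
#' post-stimulus windows plus the pre-stimulus baseline, per stimulus and
#' averaged.  Stimuli whose windows are not fully covered are excluded.
#'
#' @param rate A [spike_rate()] result (or list with `rate`, `fs`).
#' @param onsets Stimulus onset times (s).
#' @param early,steady,baseline Windows relative to onset (s, half-open).
#' @return List with per-stimulus data frame `per_stim` and the window
#'   means `early`, `steady`, `baseline` plus `n`.
#' @export
evoked_rates <- function(rate, onsets, early = c(0, 0.1),
                         steady = c(0.2, 0.5), baseline = c(-1, 0)) {
  fs <- rate$fs
  x <- rate$rate
  n <- length(x)
  rows <- lapply(onsets, function(on) {
    lo <- on + min(baseline[1], early[1])
    hi <- on + max(early[2], steady[2], baseline[2])
    if (round(lo * fs) < 0 || round(hi * fs) > n) return(NULL)
    data.frame(onset = on,
               baseline = window_mean(x, fs, on + baseline[1],
                                      on + baseline[2]),
               early = window_mean(x, fs, on + early[1], on + early[2]),
               steady = window_mean(x, fs, on + steady[1], on + steady[2]))
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0L)
    return(list(per_stim = data.frame(), early = NA_real_, steady = NA_real_,
                baseline = NA_real_, n = 0L))
  list(per_stim = per, early = mean(per$early), steady = mean(per$steady),
       baseline = mean(per$baseline), n = nrow(per))
}
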