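# Resting-state spectral analysis of delta[HbT]: multitaper PSD, log-spaced
# resampling, ordinary-least-squares power-law fitting, pre-whitening and
# vasomotion-peak metrics.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Tapers are obtained as the leading eigenvectors of the symmetric
#' tridiagonal matrix associated with the spectral-concentration problem.
#' For long traces the eigenproblem is solved at a reduced length and the
#' tapers are spline-interpolated to `n` and re-orthonormalized; the
#' concentration of each taper within the target band `[-W, W]`
#' (`W = nw / n` cycles per sample) is then computed directly from its
#' spectrum and returned as the eigenvalue weight.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5; clamped to `2 * nw - 1` with a
#'   warning if larger).
#' @param n_exact Maximum length solved exactly (larger lengths are
#'   interpolated).
#' @return List with `tapers` (n x k matrix, orthonormal columns) and
#'   `eigen` (concentration values in (0, 1]).
#' @export
dpss_tapers <- function(n, nw = 3, k = 5, n_exact = 512L) {
  kmax <- floor(2 * nw - 1)
  if (k > kmax) {
    warning(sprintf("k = %d exceeds 2*nw - 1 = %d; clamping", k, kmax))
    k <- kmax
  }
  n0 <- min(n, n_exact)
  w <- nw / n0
  tvec <- seq_len(n0) - 1L
  diag_main <- ((n0 - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  diag_off <- (tvec[-1] * (n0 - tvec[-1])) / 2
  A <- matrix(0, n0, n0)
  A[cbind(seq_len(n0), seq_len(n0))] <- diag_main
  A[cbind(seq_len(n0 - 1L), seq_len(n0 - 1L) + 1L)] <- diag_off
  A[cbind(seq_len(n0 - 1L) + 1L, seq_len(n0 - 1L))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n > n0) {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    V <- apply(V, 2L, function(v) stats::spline(x0, v, xout = x1)$y)
    V <- qr.Q(qr(V))  # re-orthonormalize after interpolation
  }
  # sign convention: symmetric tapers positive mean, others positive slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2L, j] - V[1L, j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  # concentration within [-W, W] measured on the actual tapers
  W <- nw / n
  npad <- stats::nextn(8L * n, factors = 2)
  lam <- vapply(seq_len(k), function(j) {
    sp <- Mod(stats::fft(c(V[, j], numeric(npad - n))))^2
    f <- (seq_len(npad) - 1L) / npad
    inband <- f <= W | f >= 1 - W
    sum(sp[inband]) / sum(sp)
  }, numeric(1))
  list(tapers = V, eigen = lam)
}

#' Multitaper power spectral density
#'
#' Eigenvalue-weighted average of tapered periodograms.  Returns the
#' one-sided PSD (density units: input^2 per Hz) on the Fourier grid,
#' excluding DC.
#'
#' @param x Numeric trace (demeaned internally).
#' @param fs Sampling rate (Hz).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @param tapers Optional precomputed [dpss_tapers()] result (for repeated
#'   calls on windows of equal length).
#' @return List with `freq` (Hz) and `power`.
#' @export
multitaper_psd <- function(x, fs, nw = 3, k = 5, tapers = NULL) {
  n <- length(x)
  if (n < 8L) stop("trace too short for spectral estimation")
  if (is.null(tapers)) tapers <- dpss_tapers(n, nw, k)
  V <- tapers$tapers
  lam <- tapers$eigen
  x <- x - mean(x)
  nf <- n %/% 2L
  S <- numeric(nf)
  for (j in seq_len(ncol(V))) {
    X <- stats::fft(V[, j] * x)
    S <- S + lam[j] * Mod(X[2:(nf + 1L)])^2
  }
  S <- S / sum(lam) / fs
  # one-sided: double everything except a Nyquist bin at even n
  S <- 2 * S
  if (n %% 2L == 0L) S[nf] <- S[nf] / 2
  list(freq = (1:nf) * fs / n, power = S)
}

#' Resample a spectrum onto logarithmically spaced frequency bins
#'
#' Counteracts the overrepresentation of high frequencies on a log-log scale
#' before line fitting.  Each bin reports the geometric mean of its member
#' frequencies and the arithmetic mean of their powers; empty bins are
#' dropped.
#'
#' @param freq Strictly positive frequencies (Hz), DC excluded.
#' @param power Spectral power at `freq`.
#' @param n_bins Number of log-spaced bins (>= 3).
#' @return List with binned `freq`, `power` and the member `count` per bin.
#' @export
log_resample <- function(freq, power, n_bins = 64) {
  if (n_bins < 3) stop("n_bins must be at least 3")
  if (any(freq <= 0)) stop("frequencies must be strictly positive")
  edges <- exp(seq(log(min(freq)), log(max(freq)), length.out = n_bins + 1L))
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-12)
  bin <- cut(freq, edges, labels = FALSE)
  keep <- !is.na(bin)
  gf <- tapply(log(freq[keep]), bin[keep], mean)
  mp <- tapply(power[keep], bin[keep], mean)
  cnt <- tapply(rep(1, sum(keep)), bin[keep], sum)
  list(freq = unname(exp(gf)), power = unname(as.numeric(mp)),
       count = unname(as.numeric(cnt)))
}

#' Fit a power law to a spectrum by ordinary least squares
#'
#' Fits `log10(power) = log10(a) - beta * log10(freq)` over the requested
#' band, after discarding the lowest `exclude_lowest` frequency points
#' (whose power is suppressed by detrending and finite record length).
#'
#' @param freq Frequencies (Hz), typically log-resampled.
#' @param power Spectral power.
#' @param fit_band Two-element band `c(lo, hi)` in Hz.
#' @param exclude_lowest Number of lowest-frequency points to drop.
#' @return A `power_law_fit` list: `a`, `beta` (reported positive for a
#'   decaying spectrum), fitted values and the points used.
#' @export
fit_power_law <- function(freq, power, fit_band = c(0.005, 1),
                          exclude_lowest = 2L) {
  o <- order(freq)
  freq <- freq[o]; power <- power[o]
  if (exclude_lowest > 0 && length(freq) > exclude_lowest) {
    freq <- freq[-seq_len(exclude_lowest)]
    power <- power[-seq_len(exclude_lowest)]
  }
  sel <- freq >= fit_band[1] & freq <= fit_band[2] & power > 0
  if (sum(sel) < 2L) stop("need at least 2 spectral points inside fit_band")
  if (length(unique(freq[sel])) < 2L)
    stop("degenerate spectrum: single frequency in fit band")
  lf <- log10(freq[sel]); lp <- log10(power[sel])
  fit <- stats::lm.fit(cbind(1, lf), lp)
  a <- 10^fit$coefficients[1]
  beta <- -fit$coefficients[2]
  structure(list(a = unname(a), beta = unname(beta),
                 freq = freq[sel], power = power[sel],
                 fitted = unname(a) * freq[sel]^(-unname(beta)),
                 fit_band = fit_band),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit P = a f^-beta: a = %.4g, beta = %.3f (%d points, %.3g-%.3g Hz)\n",
              x$a, x$beta, length(x$freq), x$fit_band[1], x$fit_band[2]))
  invisible(x)
}

#' Pre-whiten a spectrum and locate its dominant peak
#'
#' Divides the spectrum by the fitted power-law trend, giving the whitened
#' ratio spectrum, and locates the dominant narrowband peak inside
#' `search_band`.  Because a spectral estimator with bandwidth `smooth_bw`
#' smears a narrowband component over `[-bw, bw]` while the `1/f` trend
#' keeps falling across that interval, the *location* of the peak is taken
#' from the background-subtracted spectrum (estimate minus the
#' bandwidth-averaged model trend, lightly smoothed), which is unbiased for
#' a symmetric narrowband component; parabolic interpolation refines it
#' below grid resolution.  Peak *power* is the whitened ratio at that
#' frequency, and a whitened maximum below `min_peak` is flagged "no peak"
#' (a pure power law whitens to exactly 1).
#'
#' @param freq Frequencies (Hz), an (approximately) uniform grid.
#' @param power Spectral power at `freq`.
#' @param fit A [fit_power_law()] result.
#' @param search_band Peak search band (Hz), default `c(0.01, 0.5)`.
#' @param smooth_bw Half-bandwidth (Hz) of the spectral estimator (for a
#'   multitaper estimate, `nw * fs / n`); `NULL` or 0 disables smoothing
#'   and trend averaging.
#' @param min_peak Whitened-power threshold below which no peak is reported.
#' @return List with `whitened` (same grid as `freq`), `peak_freq`,
#'   `peak_power` (whitened units), `peak_fraction` (peak power over total
#'   whitened power) and `no_peak`.
#' @export
prewhiten_and_peak <- function(freq, power, fit, search_band = c(0.01, 0.5),
                               smooth_bw = NULL, min_peak = 1.5) {
  if (search_band[1] >= search_band[2] ||
      !any(freq >= search_band[1] & freq <= search_band[2]))
    stop("empty search band")
  trend <- fit$a * freq^(-fit$beta)
  whitened <- power / trend
  use_bw <- !is.null(smooth_bw) && smooth_bw > 0 && length(freq) > 3L
  trend_s <- if (use_bw) smeared_power_law(freq, fit$a, fit$beta, smooth_bw)
             else trend
  excess <- power - trend_s
  wdet <- whitened
  if (use_bw) {
    df <- stats::median(diff(freq))
    halfw <- max(1L, round(smooth_bw / df / 2))
    kern <- rep(1 / (2L * halfw + 1L), 2L * halfw + 1L)
    norm <- conv_same(rep(1, length(freq)), kern)
    excess <- conv_same(excess, kern) / norm
    wdet <- conv_same(whitened, kern) / norm
  }
  sel <- which(freq >= search_band[1] & freq <= search_band[2])
  # stage 1: find the peak region on the whitened ratio (noise-robust)
  ipk0 <- sel[which.max(wdet[sel])]
  # stage 2: localize within one estimator bandwidth of the candidate on the
  # background-subtracted spectrum (free of the 1/f division tilt)
  bw_here <- if (use_bw) smooth_bw else 0
  near <- which(abs(freq - freq[ipk0]) <= max(bw_here,
                                              2 * stats::median(diff(freq))))
  ipk <- near[which.max(excess[near])]
  peak_freq <- freq[ipk]
  # parabolic refinement in linear frequency
  if (ipk > 1L && ipk < length(freq)) {
    y <- excess[(ipk - 1L):(ipk + 1L)]
    d2 <- y[1] - 2 * y[2] + y[3]
    if (is.finite(d2) && d2 < 0) {
      delta <- 0.5 * (y[1] - y[3]) / d2  # vertex offset in grid units
      if (abs(delta) <= 1)
        peak_freq <- freq[ipk] + delta * (freq[ipk + 1L] - freq[ipk])
    }
  }
  peak_power <- wdet[ipk0]
  no_peak <- !is.finite(peak_power) || peak_power < min_peak
  list(whitened = whitened,
       peak_freq = if (no_peak) NA_real_ else peak_freq,
       peak_power = if (no_peak) NA_real_ else peak_power,
       peak_fraction = if (no_peak) NA_real_ else peak_power / sum(whitened),
       no_peak = no_peak)
}

# Average of a*f^-beta over the estimator bandwidth [f - bw, f + bw]
# (clipped below at half the lowest grid frequency), via the analytic
# antiderivative.
smeared_power_law <- function(freq, a, beta, bw) {
  fmin <- min(freq) / 2
  lo <- pmax(freq - bw, fmin)
  hi <- freq + bw
  if (abs(beta - 1) < 1e-8) {
    a * (log(hi) - log(lo)) / (hi - lo)
  } else {
    a * (hi^(1 - beta) - lo^(1 - beta)) / ((1 - beta) * (hi - lo))
  }
}

#' Select resting trials from a velocity trace
#'
#' A trial is "resting" when fewer than `max_move_frac` of its samples show
#' movement (velocity magnitude above `move_threshold`); the comparison is a
#' strict inequality.
#'
#' @param velocity Velocity trace.
#' @param fs Sampling rate of `velocity` (Hz).
#' @param trial_bounds Data frame or matrix with columns `start`, `end` (s).
#' @param move_threshold Movement threshold on `|velocity|`.
#' @param max_move_frac Maximum movement fraction for a resting trial.
#' @return Data frame of the kept trials with their movement fraction
#'   (possibly zero rows).
#' @export
rest_segments <- function(velocity, fs, trial_bounds, move_threshold = 0.5,
                          max_move_frac = 0.10) {
  tb <- as.data.frame(trial_bounds)
  if (!all(c("start", "end") %in% names(tb)))
    names(tb)[1:2] <- c("start", "end")
  frac <- vapply(seq_len(nrow(tb)), function(i) {
    idx <- win_idx(fs, tb$start[i], tb$end[i], length(velocity))
    if (length(idx) == 0L) return(NA_real_)
    mean(abs(velocity[idx]) > move_threshold)
  }, numeric(1))
  keep <- !is.na(frac) & frac < max_move_frac
  out <- tb[keep, c("start", "end"), drop = FALSE]
  out$move_frac <- frac[keep]
  rownames(out) <- NULL
  out
}

#' Full resting-state spectrum analysis of a delta[HbT] trace
#'
#' Convenience wrapper chaining [multitaper_psd()], [log_resample()],
#' [fit_power_law()] and [prewhiten_and_peak()] (pre-whitening runs on the
#' raw Fourier grid, detection smoothed over the multitaper bandwidth).
#'
#' @param hbt delta[HbT] trace (uM).
#' @param fs Sampling rate (Hz).
#' @param nw,k Multitaper parameters.
#' @param n_bins Log-resampling bins for the power-law fit.
#' @param fit_band,exclude_lowest Passed to [fit_power_law()].
#' @param search_band Passed to [prewhiten_and_peak()].
#' @return A `spectrum_fit` object: the raw spectrum, binned spectrum,
#'   power-law coefficients `a` and `beta`, whitened spectrum and peak
#'   metrics.
#' @export
spectrum_fit <- function(hbt, fs, nw = 3, k = 5, n_bins = 64,
                         fit_band = c(0.005, 1), exclude_lowest = 2L,
                         search_band = c(0.01, 0.5)) {
  psd <- multitaper_psd(hbt, fs, nw, k)
  spectrum_fit_psd(psd$freq, psd$power, smooth_bw = nw * fs / length(hbt),
                   n_bins = n_bins, fit_band = fit_band,
                   exclude_lowest = exclude_lowest,
                   search_band = search_band)
}

#' Power-law fit and peak detection on a precomputed spectrum
#'
#' The spectrum half of [spectrum_fit()], applicable to e.g. a
#' session-averaged power spectrum.  A first power-law fit locates any
#' narrowband peak; when one is found, the power law is refit with the bins
#' within `3 * smooth_bw` of the peak excluded (so the peak cannot inflate
#' the exponent) and whitening/detection is repeated with the refined trend.
#'
#' @param freq,power One-sided spectrum (DC excluded).
#' @param smooth_bw Estimator half-bandwidth in Hz (see
#'   [prewhiten_and_peak()]).
#' @inheritParams spectrum_fit
#' @return A `spectrum_fit` object.
#' @export
spectrum_fit_psd <- function(freq, power, smooth_bw, n_bins = 64,
                             fit_band = c(0.005, 1), exclude_lowest = 2L,
                             search_band = c(0.01, 0.5)) {
  binned <- log_resample(freq, power, n_bins)
  fit <- fit_power_law(binned$freq, binned$power, fit_band, exclude_lowest)
  pk <- prewhiten_and_peak(freq, power, fit, search_band = search_band,
                           smooth_bw = smooth_bw)
  if (!pk$no_peak) {
    keep <- abs(binned$freq - pk$peak_freq) > 3 * smooth_bw
    fit2 <- tryCatch(
      fit_power_law(binned$freq[keep], binned$power[keep], fit_band,
                    exclude_lowest),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      pk <- prewhiten_and_peak(freq, power, fit, search_band = search_band,
                               smooth_bw = smooth_bw)
    }
  }
  structure(list(freq = freq, power = power, binned = binned,
                 a = fit$a, beta = fit$beta, fit = fit,
                 whitened = pk$whitened, peak_freq = pk$peak_freq,
                 peak_power = pk$peak_power,
                 peak_fraction = pk$peak_fraction, no_peak = pk$no_peak),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Resting-state spectrum: beta = %.3f (a = %.3g)\n", x$beta, x$a))
  if (isTRUE(x$no_peak)) {
    cat("  no whitened-spectrum peak detected\n")
  } else {
    cat(sprintf("  whitened peak at %.3f Hz (power %.2f, fraction %.4f)\n",
                x$peak_freq, x$peak_power, x$peak_fraction))
  }
  invisible(x)
}
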