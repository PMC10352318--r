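# Hemodynamics: reflectance -> delta[HbT] conversion and stimulus-evoked
# response metrics.

#' Optical constants for the Beer-Lambert conversion
#'
#' Wavelength-dependent constants at the 530 nm hemoglobin isosbestic point.
#' Defaults are representative literature values for mouse cortex imaged
#' through a thinned skull: an estimated photon pathlength of about 0.1 cm
#' and a total-hemoglobin extinction coefficient of 0.039 per uM per cm.
#' Absolute delta[HbT] values scale with `1 / (pathlength_X * extinction_xi)`,
#' so analyses that compare conditions within a session are invariant to this
#' product.
#'
#' @param pathlength_X Wavelength-dependent pathlength estimate (cm).
#' @param extinction_xi Molecular extinction coefficient (uM^-1 cm^-1).
#' @return A named list of class `optical_constants`.
#' @export
optical_constants <- function(pathlength_X = 0.1, extinction_xi = 0.039) {
  stopifnot_scalar(pathlength_X, "pathlength_X", positive = TRUE)
  stopifnot_scalar(extinction_xi, "extinction_xi", positive = TRUE)
  structure(list(pathlength_X = pathlength_X, extinction_xi = extinction_xi),
            class = "optical_constants")
}

#' Average pixel intensity over a region of interest
#'
#' @param frame_stack 3-D numeric array (rows x cols x frames).
#' @param roi_mask Logical matrix matching the frame dimensions.
#' @return Numeric vector: per-frame arithmetic mean over masked pixels.
#' @export
roi_mean <- function(frame_stack, roi_mask) {
  if (length(dim(frame_stack)) != 3L)
    stop("frame_stack must be a rows x cols x frames array")
  if (!is.logical(roi_mask) ||
      !identical(dim(roi_mask), dim(frame_stack)[1:2]))
    stop("roi_mask must be a logical matrix matching the frame dimensions")
  if (!any(roi_mask)) stop("roi_mask is empty")
  npx <- sum(roi_mask)
  apply(frame_stack, 3L, function(fr) sum(fr[roi_mask]) / npx)
}

#' Convert reflectance intensity to delta[HbT]
#'
#' Modified Beer-Lambert law:
#' `dHbT(t) = -ln(I(t) / I0) / (X * xi)`, where `I0` is the mean intensity
#' over the baseline window.  Decreased reflectance (more absorbing
#' hemoglobin) maps to positive delta[HbT].
#'
#' @param intensity Strictly positive intensity trace.
#' @param fs Sampling rate (Hz).
#' @param baseline_window Two-element `c(start, end)` in seconds, half-open,
#'   over which `I0` is averaged.
#' @param constants An [optical_constants()] object.
#' @return delta[HbT] trace in uM.
#' @export
beer_lambert_hbt <- function(intensity, fs, baseline_window = NULL,
                             constants = optical_constants()) {
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be strictly positive and finite")
  n <- length(intensity)
  if (is.null(baseline_window)) baseline_window <- c(0, n / fs)
  idx <- win_idx(fs, baseline_window[1], baseline_window[2], n)
  if (length(idx) == 0L) stop("baseline window contains no samples")
  i0 <- mean(intensity[idx])
  if (i0 <= 0) stop("baseline intensity must be positive")
  -log(intensity / i0) /
    (constants$pathlength_X * constants$extinction_xi)
}

#' Gamma-variate response template
#'
#' `h(t) = A * (t/tp)^alpha * exp(alpha * (1 - t/tp))` for `t > 0`, zero
#' otherwise, with the shape `alpha` solved numerically so that the
#' full-width at half-maximum equals `fwhm`.  Peaks at exactly
#' (`time_to_peak`, `peak_amp`).
#'
#' @param t Times relative to onset (s); values `<= 0` return 0.
#' @param peak_amp Peak amplitude.
#' @param time_to_peak Time of the peak (s).
#' @param fwhm Full width at half maximum (s).
#' @return Numeric vector of template values.
#' @export
gamma_variate <- function(t, peak_amp, time_to_peak, fwhm) {
  alpha <- gamma_variate_alpha(fwhm / time_to_peak)
  out <- numeric(length(t))
  pos <- t > 0
  u <- t[pos] / time_to_peak
  out[pos] <- peak_amp * exp(alpha * (log(u) + 1 - u))
  out
}

# FWHM / time-to-peak ratio of the unit gamma-variate with shape alpha.
gamma_variate_fwhm_ratio <- function(alpha) {
  g <- function(u) alpha * (log(u) + 1 - u) + log(2)
  u_lo <- exp(-log(2) / alpha - 6)  # g(u_lo) <= -5 * alpha < 0
  u1 <- stats::uniroot(g, c(u_lo, 1), tol = 1e-12)$root
  up <- 2
  while (g(up) > 0) up <- up * 2
  u2 <- stats::uniroot(g, c(1, up), tol = 1e-12)$root
  u2 - u1
}

gamma_variate_alpha <- function(target_ratio) {
  if (!is.finite(target_ratio) || target_ratio <= 0)
    stop("fwhm / time_to_peak must be positive")
  stats::uniroot(function(a) gamma_variate_fwhm_ratio(a) - target_ratio,
                 c(0.02, 2000), tol = 1e-10)$root
}

#' Stimulus-triggered average of a trace
#'
#' Cuts peri-stimulus snippets covering `[-pre_s, post_s)` around each onset,
#' subtracts each snippet's own pre-stimulus baseline (mean over
#' `baseline_window`), and averages.  Onsets without full window coverage are
#' excluded.
#'
#' @param x Trace (e.g. delta[HbT], uM).
#' @param fs Sampling rate (Hz).
#' @param onsets Stimulus onset times (s).
#' @param pre_s,post_s Window extent before/after onset (s).
#' @param baseline_window Baseline-correction window relative to onset,
#'   default `c(-3, 0)` (half-open).  `NULL` disables correction.
#' @return An `evoked_average` object: list with `time` (s, relative to
#'   onset), `mean`, `sd`, `n`, and the snippet matrix.
#' @export
evoked_average <- function(x, fs, onsets, pre_s = 5, post_s = 15,
                           baseline_window = c(-3, 0)) {
  n <- length(x)
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  rel_idx <- seq.int(-npre, npost - 1L)
  time <- rel_idx / fs
  snips <- list()
  for (on in onsets) {
    i0 <- round(on * fs)  # sample index (0-based) at onset
    idx <- i0 + rel_idx + 1L
    if (idx[1] < 1L || idx[length(idx)] > n) next
    s <- x[idx]
    if (!is.null(baseline_window)) {
      b <- which(time >= baseline_window[1] & time < baseline_window[2])
      s <- s - mean(s[b])
    }
    snips[[length(snips) + 1L]] <- s
  }
  if (length(snips) == 0L) stop("no stimulus has full peri-stimulus coverage")
  m <- do.call(rbind, snips)
  structure(list(time = time,
                 mean = colMeans(m),
                 sd = apply(m, 2L, stats::sd),
                 n = nrow(m),
                 snippets = m),
            class = "evoked_average")
}

#' Evoked-response metrics of a peri-stimulus trace
#'
#' Peak amplitude and its latency within the search window, full width at
#' half maximum by linear interpolation of the half-max crossings flanking
#' the peak, the mean response 0.5-3 s after onset, and the undershoot mean
#' 5-15 s after onset.  A non-positive peak is flagged `no_clear_peak` (all
#' peak-dependent metrics `NA`); a peak whose half-max recovery never occurs
#' within the trace is flagged `fwhm_undefined`.
#'
#' @param time Peri-stimulus time axis (s, onset at 0).
#' @param trace Peri-stimulus response (e.g. mean of [evoked_average()]).
#' @param search_window Peak search window, default `c(0, 5)` s (half-open).
#' @param early_window,undershoot_window Averaging windows (s, half-open).
#' @return An `evoked_metrics` object: list with `peak_amp`, `time_to_peak`,
#'   `fwhm`, `early_mean`, `undershoot_mean` and logical flags.
#' @export
evoked_metrics <- function(time, trace, search_window = c(0, 5),
                           early_window = c(0.5, 3),
                           undershoot_window = c(5, 15)) {
  if (inherits(time, "evoked_average")) {
    trace <- time$mean
    time <- time$time
  }
  stopifnot(length(time) == length(trace))
  inw <- which(time >= search_window[1] & time < search_window[2])
  if (length(inw) == 0L) stop("search window is empty")
  ipk <- inw[which.max(trace[inw])]
  peak <- trace[ipk]
  early <- mean(trace[time >= early_window[1] & time < early_window[2]])
  under <- mean(trace[time >= undershoot_window[1] &
                        time < undershoot_window[2]])
  if (!is.finite(peak) || peak <= 0) {
    return(structure(list(peak_amp = NA_real_, time_to_peak = NA_real_,
                          fwhm = NA_real_, early_mean = early,
                          undershoot_mean = under, no_clear_peak = TRUE,
                          fwhm_undefined = TRUE),
                     class = "evoked_metrics"))
  }
  half <- peak / 2
  # rising crossing: last time before the peak the trace is below half-max
  left <- NA_real_
  for (i in seq.int(ipk, 2L)) {
    if (trace[i - 1L] < half && trace[i] >= half) {
      left <- time[i - 1L] + (time[i] - time[i - 1L]) *
        (half - trace[i - 1L]) / (trace[i] - trace[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (ipk < length(trace)) {
    for (i in seq.int(ipk, length(trace) - 1L)) {
      if (trace[i] >= half && trace[i + 1L] < half) {
        right <- time[i] + (time[i + 1L] - time[i]) *
          (trace[i] - half) / (trace[i] - trace[i + 1L])
        break
      }
    }
  }
  fwhm <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  structure(list(peak_amp = peak, time_to_peak = time[ipk], fwhm = fwhm,
                 early_mean = early, undershoot_mean = under,
                 no_clear_peak = FALSE,
                 fwhm_undefined = is.na(fwhm)),
            class = "evoked_metrics")
}

#' @export
print.evoked_metrics <- function(x, ...) {
  if (isTRUE(x$no_clear_peak)) {
    cat("Evoked metrics: no clear peak\n")
  } else {
    cat(sprintf(
      "Evoked metrics: peak %.2f uM at %.2f s, FWHM %s s\n",
      x$peak_amp, x$time_to_peak,
      if (is.na(x$fwhm)) "undefined" else sprintf("%.2f", x$fwhm)))
  }
  cat(sprintf("  early mean [0.5,3) s: %.2f uM;  undershoot [5,15) s: %.2f uM\n",
              x$early_mean, x$undershoot_mean))
  invisible(x)
}
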