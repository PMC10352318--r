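# Transition-triggered and stimulus-triggered analyses: qualified arousal
# transitions, peri-transition delta[HbT] statistics, evoked responses split
# by pre-stimulus state, and peri-stimulus awake probability.

#' Extract qualified arousal-state transitions
#'
#' A bout boundary qualifies when the preceding and following bouts each
#' last at least `min_pre` / `min_post` seconds and both analysis windows
#' fit inside the recording.  For each event the baseline mean is taken
#' over `[t - 15, t - 5)` and the response mean over `[t + 5, t + 15)`
#' (half-open windows, entirely inside the flanking bouts), and
#' `delta = response - baseline`.
#'
#' @param hyp A `hypnogram` (or precomputed [extract_bouts()] data frame).
#' @param hbt delta[HbT] trace (uM).
#' @param fs Sampling rate of `hbt` (Hz).
#' @param min_pre,min_post Minimum flanking bout durations (s).
#' @param baseline_window,response_window Windows relative to the boundary
#'   (s).
#' @return Data frame of class `transition_events` with columns `from`,
#'   `to`, `t`, `baseline_mean`, `response_mean`, `delta` (possibly zero
#'   rows).
#' @export
find_transitions <- function(hyp, hbt, fs, min_pre = 15, min_post = 15,
                             baseline_window = c(-15, -5),
                             response_window = c(5, 15)) {
  bouts <- if (is.data.frame(hyp) && "duration" %in% names(hyp)) hyp
           else extract_bouts(hyp)
  n <- length(hbt)
  dur <- n / fs
  rows <- list()
  if (nrow(bouts) >= 2L) {
    for (i in seq_len(nrow(bouts) - 1L)) {
      t <- bouts$end[i]
      if (bouts$duration[i] < min_pre) next
      if (bouts$duration[i + 1L] < min_post) next
      if (t + baseline_window[1] < 0 || t + response_window[2] > dur) next
      b <- window_mean(hbt, fs, t + baseline_window[1],
                       t + baseline_window[2])
      r <- window_mean(hbt, fs, t + response_window[1],
                       t + response_window[2])
      rows[[length(rows) + 1L]] <- data.frame(
        from = bouts$state[i], to = bouts$state[i + 1L], t = t,
        baseline_mean = b, response_mean = r, delta = r - b,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(from = character(0), to = character(0),
                         t = numeric(0), baseline_mean = numeric(0),
                         response_mean = numeric(0), delta = numeric(0))
  class(out) <- c("transition_events", "data.frame")
  out
}

#' Peri-transition average trace
#'
#' Averages raw (uncorrected) delta[HbT] snippets aligned at the transition
#' time for one transition type, preserving the absolute blood-volume levels
#' on either side of the transition.
#'
#' @param hbt delta[HbT] trace (uM).
#' @param fs Sampling rate (Hz).
#' @param events [find_transitions()] output.
#' @param from,to Transition type to average.
#' @param window Half-window (s); snippets span `[-window, window)`.
#' @return List with `time`, `mean`, `sd`, `n`; `n = 0` (flagged empty) when
#'   no event of the type has full coverage.
#' @export
peri_transition_average <- function(hbt, fs, events, from, to, window = 30) {
  ev <- events[events$from == from & events$to == to, , drop = FALSE]
  nw <- round(window * fs)
  rel <- seq.int(-nw, nw - 1L)
  time <- rel / fs
  snips <- list()
  for (t in ev$t) {
    idx <- round(t * fs) + rel + 1L
    if (idx[1] < 1L || idx[length(idx)] > length(hbt)) next
    snips[[length(snips) + 1L]] <- hbt[idx]
  }
  if (length(snips) == 0L)
    return(list(time = time, mean = rep(NA_real_, length(time)),
                sd = rep(NA_real_, length(time)), n = 0L, empty = TRUE))
  m <- do.call(rbind, snips)
  list(time = time, mean = colMeans(m), sd = apply(m, 2L, stats::sd),
       n = nrow(m), empty = FALSE)
}

#' Per-type transition statistics
#'
#' Mean, SD and count of the baseline-to-response delta for every observed
#' `from -> to` pair.  Types observed once report `sd = NA` (flagged);
#' rarely observed types are reported with their `n`, not suppressed.
#'
#' @param events [find_transitions()] output.
#' @return Data frame with `from`, `to`, `n`, `mean_delta`, `sd_delta`,
#'   `single_event`.
#' @export
transition_stats <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(from = character(0), to = character(0), n = integer(0),
                      mean_delta = numeric(0), sd_delta = numeric(0),
                      single_event = logical(0)))
  key <- interaction(events$from, events$to, drop = TRUE, sep = "->")
  sp <- split(events$delta, key)
  out <- do.call(rbind, lapply(names(sp), function(k) {
    d <- sp[[k]]
    parts <- strsplit(k, "->", fixed = TRUE)[[1]]
    data.frame(from = parts[1], to = parts[2], n = length(d),
               mean_delta = mean(d),
               sd_delta = if (length(d) > 1L) stats::sd(d) else NA_real_,
               single_event = length(d) == 1L, stringsAsFactors = FALSE)
  }))
  out[order(-out$n), , drop = FALSE]
}

#' Label stimuli by pre-stimulus arousal state
#'
#' Each onset is labelled with the state of the 5-s bin immediately
#' preceding the bin containing it, so the label cannot be contaminated by
#' a stimulus-triggered awakening within the onset bin.  Onsets inside the
#' first bin are excluded.
#'
#' @param onsets Stimulus onset times (s).
#' @param hyp A `hypnogram`.
#' @return Data frame with `onset` and `state` (excluded onsets dropped; the
#'   number removed is in attribute `n_excluded`).
#' @export
split_stimuli_by_state <- function(onsets, hyp) {
  bin <- attr(hyp, "bin")
  if (is.null(bin)) bin <- hyp$bin_end[1] - hyp$bin_start[1]
  j <- floor(onsets / bin) + 1L      # bin containing the onset
  prev <- j - 1L
  ok <- prev >= 1L & j <= nrow(hyp)
  out <- data.frame(onset = onsets[ok], state = hyp$label[prev[ok]],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Stimulus-evoked averages split by pre-stimulus state
#'
#' Per-state peri-stimulus averages (same snippet conventions as
#' [evoked_average()]) for every state with at least `min_n` usable stimuli,
#' plus the pooled average over all stimuli of the reported states.  The
#' pooled trace equals the count-weighted mean of the per-state traces.
#'
#' @param hbt delta[HbT] trace (uM).
#' @param fs Sampling rate (Hz).
#' @param labeled [split_stimuli_by_state()] output.
#' @param min_n Minimum stimuli per reported state.
#' @param ... Passed to [evoked_average()].
#' @return List with `by_state` (named list of `evoked_average` objects),
#'   `pooled`, and `excluded` (states observed fewer than `min_n` times).
#' @export
evoked_by_state <- function(hbt, fs, labeled, min_n = 3, ...) {
  states <- unique(labeled$state)
  usable <- function(on) {
    ea <- tryCatch(evoked_average(hbt, fs, on, ...), error = function(e) NULL)
    ea
  }
  by_state <- list()
  counts <- integer(0)
  for (s in states) {
    ea <- usable(labeled$onset[labeled$state == s])
    if (!is.null(ea) && ea$n >= min_n) {
      by_state[[s]] <- ea
      counts[s] <- ea$n
    }
  }
  excluded <- setdiff(states, names(by_state))
  pooled_onsets <- labeled$onset[labeled$state %in% names(by_state)]
  pooled <- if (length(pooled_onsets)) usable(pooled_onsets) else NULL
  list(by_state = by_state, pooled = pooled, excluded = excluded,
       n_by_state = counts)
}

#' Peri-stimulus probability of being awake
#'
#' For each peri-stimulus bin offset, the fraction of stimuli whose
#' hypnogram label at that offset is an awake state.  `P(awake)` and
#' `P(asleep)` are complementary at every offset.  Only onsets with full
#' window coverage contribute.
#'
#' @param hyp A `hypnogram`.
#' @param onsets Stimulus onset times (s).
#' @param window Half-window (s) around the onset.
#' @param awake_states Labels counted as awake; defaults to the age's awake
#'   set.
#' @return Data frame with `peri_time` (bin offset start, s), `p_awake`,
#'   `p_asleep`, `n`.
#' @export
peristim_awake_probability <- function(hyp, onsets, window = 30,
                                       awake_states = NULL) {
  bin <- attr(hyp, "bin")
  if (is.null(bin)) bin <- hyp$bin_end[1] - hyp$bin_start[1]
  if (is.null(awake_states)) {
    ag <- attr(hyp, "age_group")
    awake_states <- if (!is.null(ag)) age_defaults(ag)$awake_states
                    else c("active_awake", "quiescent_awake")
  }
  nb <- nrow(hyp)
  koff <- seq.int(-ceiling(window / bin), ceiling(window / bin) - 1L)
  j0 <- floor(onsets / bin) + 1L
  ok <- (j0 + koff[1]) >= 1L & (j0 + koff[length(koff)]) <= nb
  j0 <- j0[ok]
  if (length(j0) == 0L) stop("no stimulus with full peri-stimulus coverage")
  awake <- hyp$label %in% awake_states
  p <- vapply(koff, function(k) mean(awake[j0 + k]), numeric(1))
  data.frame(peri_time = koff * bin, p_awake = p, p_asleep = 1 - p,
             n = length(j0))
}
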