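# Rule-based arousal-state scoring in 5-s bins from EMG power, LFP band
# powers and locomotion, with bout extraction and sleep-architecture
# statistics.

#' Per-bin scoring features
#'
#' Aggregates the scoring channels into non-overlapping bins (default 5 s):
#' the median EMG power, its within-bin maximum (twitch marker), median
#' delta/theta/gamma LFP power, and the fraction of samples showing
#' locomotion.  Channels may be sampled at different rates but must span the
#' same session; a trailing partial bin is dropped.
#'
#' @param emg_power EMG power trace (see [emg_power()]).
#' @param delta,theta,gamma LFP band-power traces (see [band_power_trace()]).
#' @param velocity Velocity trace.
#' @param fs_emg,fs_lfp,fs_vel Sampling rates (Hz) of the respective traces.
#' @param bin Bin length (s).
#' @param move_threshold Velocity magnitude above which a sample counts as
#'   movement.
#' @return Data frame with `bin_start`, `bin_end` and the feature columns.
#' @export
bin_features <- function(emg_power, delta, theta, gamma, velocity,
                         fs_emg, fs_lfp = fs_emg, fs_vel, bin = 5,
                         move_threshold = 0.5) {
  durs <- c(length(emg_power) / fs_emg, length(delta) / fs_lfp,
            length(theta) / fs_lfp, length(gamma) / fs_lfp,
            length(velocity) / fs_vel)
  if (diff(range(durs)) > bin)
    stop("scoring channels span different durations; inputs are misaligned")
  dur <- min(durs)
  nb <- floor(dur / bin)
  if (nb < 1L) stop("session shorter than one bin")
  bin_med <- function(x, fs) {
    vapply(seq_len(nb), function(k) {
      stats::median(x[win_idx(fs, (k - 1) * bin, k * bin, length(x))])
    }, numeric(1))
  }
  bin_max <- function(x, fs) {
    vapply(seq_len(nb), function(k) {
      max(x[win_idx(fs, (k - 1) * bin, k * bin, length(x))])
    }, numeric(1))
  }
  move <- abs(velocity) > move_threshold
  move_frac <- vapply(seq_len(nb), function(k) {
    mean(move[win_idx(fs_vel, (k - 1) * bin, k * bin, length(move))])
  }, numeric(1))
  data.frame(bin_start = (seq_len(nb) - 1L) * bin,
             bin_end = seq_len(nb) * bin,
             emg_med = bin_med(emg_power, fs_emg),
             emg_max = bin_max(emg_power, fs_emg),
             delta_med = bin_med(delta, fs_lfp),
             theta_med = bin_med(theta, fs_lfp),
             gamma_med = bin_med(gamma, fs_lfp),
             move_frac = move_frac)
}

#' Resolve scoring thresholds from the session's feature distribution
#'
#' The EMG atonia threshold separates the bimodal distribution of per-bin
#' log EMG power: `"cluster"` (default) places it midway between the two
#' k-means centers (deterministic quantile-based initialization);
#' `"percentile"` uses a fixed percentile of the session distribution.
#' REM/NREM separation uses a fixed theta/delta power ratio, and twitches
#' are within-bin EMG excursions reaching awake-like amplitude while the
#' bin median stays atonic.
#'
#' @param features [bin_features()] output.
#' @param method `"cluster"` or `"percentile"`.
#' @param atonia_percentile Percentile used by the `"percentile"` method.
#' @param theta_delta_ratio REM threshold on median theta / median delta.
#' @param move_frac Minimum within-bin movement fraction for active wake
#'   (0.5 keeps bin labels majority-consistent, so state boundaries are not
#'   systematically pulled toward the awake side).
#' @return Named list of thresholds used by [classify_bins()].
#' @export
score_thresholds <- function(features, method = c("cluster", "percentile"),
                             atonia_percentile = 0.30,
                             theta_delta_ratio = 1, move_frac = 0.5) {
  method <- match.arg(method)
  le <- log(pmax(features$emg_med, .Machine$double.xmin))
  if (method == "cluster" && length(unique(le)) > 1L) {
    centers <- stats::quantile(le, c(0.1, 0.9), names = FALSE)
    if (diff(centers) < 1e-9) {
      atonia <- exp(stats::quantile(le, atonia_percentile, names = FALSE))
    } else {
      km <- stats::kmeans(le, centers = matrix(centers, ncol = 1))
      atonia <- exp(mean(range(km$centers)))
    }
  } else {
    atonia <- exp(stats::quantile(le, atonia_percentile, names = FALSE))
  }
  list(emg_atonia = unname(atonia),
       theta_delta_ratio = theta_delta_ratio,
       move_frac = move_frac,
       twitch_emg = unname(atonia))
}

#' Classify 5-s bins into arousal states
#'
#' Decision rules mirroring manual scoring practice: locomotion means active
#' awake; otherwise EMG tone above the atonia threshold means quiescent
#' awake; among atonic bins, P15/adult animals are REM when the theta/delta
#' ratio is high and NREM otherwise, while P10 animals are active asleep
#' when myoclonic twitches are present and quiescent asleep otherwise.
#'
#' @param features [bin_features()] output.
#' @param age_group `"P10"`, `"P15"` or `"adult"`.
#' @param thresholds Optional [score_thresholds()] list; resolved from the
#'   session when `NULL`.
#' @return A `hypnogram` object: data frame `bin_start`, `bin_end`, `label`
#'   with attributes `age_group`, `bin` and `states`.
#' @export
classify_bins <- function(features, age_group = c("P15", "P10", "adult"),
                          thresholds = NULL) {
  age_group <- match.arg(age_group)
  tab <- age_defaults(age_group)
  if (is.null(thresholds)) thresholds <- score_thresholds(features)
  atonic <- features$emg_med <= thresholds$emg_atonia
  moving <- features$move_frac > thresholds$move_frac
  lab <- character(nrow(features))
  lab[moving] <- "active_awake"
  lab[!moving & !atonic] <- "quiescent_awake"
  asleep <- !moving & atonic
  if (age_group == "P10") {
    twitchy <- features$emg_max > thresholds$twitch_emg
    lab[asleep & twitchy] <- "active_asleep"
    lab[asleep & !twitchy] <- "quiescent_asleep"
  } else {
    rem <- features$theta_med / pmax(features$delta_med,
                                     .Machine$double.xmin) >
      thresholds$theta_delta_ratio
    lab[asleep & rem] <- "REM"
    lab[asleep & !rem] <- "NREM"
  }
  hyp <- data.frame(bin_start = features$bin_start,
                    bin_end = features$bin_end, label = lab,
                    stringsAsFactors = FALSE)
  structure(hyp, class = c("hypnogram", "data.frame"),
            age_group = age_group, bin = features$bin_end[1] -
              features$bin_start[1], states = tab$states)
}

#' Arousal-state scoring of a recording session
#'
#' Runs the full chain [emg_power()] + [band_power_trace()] +
#' [bin_features()] + [classify_bins()] on a `recording_session`.
#'
#' @param session A [recording_session()].
#' @param thresholds Optional [score_thresholds()] list.
#' @param bin Bin length (s).
#' @param smooth Relabel isolated single-bin flickers to their flanking
#'   state ([smooth_hypnogram()]); on by default.  A single bin of e.g.
#'   twitch-free atonia inside an active-sleep bout is read as the bout
#'   continuing, as a human scorer would.
#' @return A `hypnogram`.
#' @export
score_session <- function(session, thresholds = NULL, bin = 5,
                          smooth = TRUE) {
  suppressWarnings(ep <- emg_power(session$emg, session$fs_raw))
  de <- band_power_trace(session$lfp, session$fs_raw, c(1, 4))
  th <- band_power_trace(session$lfp, session$fs_raw, c(4, 10))
  ga <- band_power_trace(session$lfp, session$fs_raw, c(40, 100))
  feats <- bin_features(ep, de, th, ga, session$velocity,
                        fs_emg = session$fs_raw, fs_lfp = session$fs_raw,
                        fs_vel = session$fs_vel, bin = bin)
  hyp <- classify_bins(feats, session$age_group, thresholds)
  if (smooth) hyp <- smooth_hypnogram(hyp)
  hyp
}

#' Ground-truth hypnogram from a generator state sequence
#'
#' Majority (time-weighted) state per bin; the oracle against which scored
#' hypnograms are compared.
#'
#' @param truth A `ground_truth` object.
#' @param bin Bin length (s).
#' @return A `hypnogram`.
#' @export
truth_hypnogram <- function(truth, bin = 5) {
  nb <- floor(truth$duration / bin)
  seq_tab <- truth$state_sequence
  states <- if (truth$age_group %in% c("P10", "P15", "adult"))
    age_defaults(truth$age_group)$states else unique(seq_tab$state)
  lab <- vapply(seq_len(nb), function(k) {
    a <- (k - 1) * bin; b <- k * bin
    ov <- pmin(seq_tab$end, b) - pmax(seq_tab$start, a)
    ov[ov < 0] <- 0
    w <- tapply(ov, seq_tab$state, sum)
    names(w)[which.max(w)]
  }, character(1))
  hyp <- data.frame(bin_start = (seq_len(nb) - 1L) * bin,
                    bin_end = seq_len(nb) * bin, label = lab,
                    stringsAsFactors = FALSE)
  structure(hyp, class = c("hypnogram", "data.frame"),
            age_group = truth$age_group, bin = bin,
            states = states)
}

#' Merge isolated single-bin states into their flanking state
#'
#' A bin whose two neighbours agree with each other but not with it is
#' relabelled to the flanking state (a scoring-flicker smoother).
#'
#' @param hyp A `hypnogram`.
#' @return The smoothed `hypnogram`.
#' @export
smooth_hypnogram <- function(hyp) {
  lab <- hyp$label
  n <- length(lab)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (lab[i - 1L] == lab[i + 1L] && lab[i] != lab[i - 1L])
        lab[i] <- lab[i - 1L]
    }
  }
  hyp$label <- lab
  hyp
}

#' Extract bouts (maximal runs of one state) from a hypnogram
#'
#' @param hyp A `hypnogram`.
#' @param smooth Apply [smooth_hypnogram()] first (default `TRUE`).
#' @return Data frame with `state`, `start`, `end`, `duration` (s); adjacent
#'   bouts always differ in state.
#' @export
extract_bouts <- function(hyp, smooth = TRUE) {
  if (nrow(hyp) == 0L) stop("empty hypnogram")
  if (smooth) hyp <- smooth_hypnogram(hyp)
  r <- rle(hyp$label)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1L
  data.frame(state = r$values,
             start = hyp$bin_start[istart],
             end = hyp$bin_end[iend],
             duration = hyp$bin_end[iend] - hyp$bin_start[istart],
             stringsAsFactors = FALSE)
}

#' Fraction of session time in each state
#'
#' @param hyp A `hypnogram`.
#' @return Named numeric vector over the age's state set; sums to 1.
#' @export
state_fractions <- function(hyp) {
  if (nrow(hyp) == 0L) stop("empty hypnogram")
  states <- attr(hyp, "states")
  if (is.null(states)) states <- unique(hyp$label)
  f <- table(factor(hyp$label, levels = states)) / nrow(hyp)
  stats::setNames(as.numeric(f), states)
}

#' Bout-duration survival curve and median
#'
#' Empirical survival `S(t) = fraction of bouts longer than t`; the median
#' is the smallest observed duration at which `S` drops to 0.5 or below.
#'
#' @param bouts [extract_bouts()] output.
#' @param state State label to summarize.
#' @return List with `time`, `surv`, `median` (s) and `n`; `n = 0` with
#'   `median = NA` when the state never occurs.
#' @export
bout_survival <- function(bouts, state) {
  d <- sort(bouts$duration[bouts$state == state])
  if (length(d) == 0L)
    return(list(time = numeric(0), surv = numeric(0), median = NA_real_,
                n = 0L))
  tt <- c(0, unique(d))
  surv <- vapply(tt, function(t) mean(d > t), numeric(1))
  med <- tt[which(surv <= 0.5)[1]]
  list(time = tt, surv = surv, median = med, n = length(d))
}

#' Classification accuracy of a scored hypnogram against ground truth
#'
#' @param scored,truth_hyp `hypnogram` objects on the same bin grid.
#' @return Fraction of bins with matching labels.
#' @export
scoring_accuracy <- function(scored, truth_hyp) {
  nb <- min(nrow(scored), nrow(truth_hyp))
  mean(scored$label[seq_len(nb)] == truth_hyp$label[seq_len(nb)])
}
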