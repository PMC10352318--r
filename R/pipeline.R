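# Session container, plain-text I/O and pipeline orchestration.

#' Recording-session container
#'
#' Bundles the aligned channels of one imaging/electrophysiology session:
#' delta[HbT] (uM), raw nuchal EMG and hippocampal LFP, treadmill velocity,
#' stimulus onsets and metadata.  All channels share the session clock
#' (t = 0 at session start).
#'
#' @param hbt delta[HbT] trace (uM) at `fs_hbt`.
#' @param fs_hbt Hemodynamic sampling rate (Hz).
#' @param emg,lfp Raw traces at `fs_raw`.
#' @param fs_raw Raw electrophysiology sampling rate (Hz).
#' @param velocity Velocity trace at `fs_vel`.
#' @param fs_vel Velocity sampling rate (Hz).
#' @param stim_onsets Sorted stimulus onset times (s).
#' @param age_group `"P10"`, `"P15"` or `"adult"`.
#' @param duration Session length (s).
#' @param subject_id Subject identifier.
#' @param trial_len Trial length for resting-trial selection (s; sessions
#'   are acquired in sequential 5-min trials).
#' @param truth Optional generator `ground_truth`.
#' @param config Optional generator config.
#' @return A validated `recording_session` object.
#' @export
recording_session <- function(hbt, fs_hbt, emg, lfp, fs_raw, velocity,
                              fs_vel, stim_onsets = numeric(0),
                              age_group = "P15", duration = NULL,
                              subject_id = "subject", trial_len = 300,
                              truth = NULL, config = NULL) {
  if (is.null(duration)) duration <- length(hbt) / fs_hbt
  s <- structure(list(hbt = hbt, fs_hbt = fs_hbt, emg = emg, lfp = lfp,
                      fs_raw = fs_raw, velocity = velocity, fs_vel = fs_vel,
                      stim_onsets = stim_onsets, age_group = age_group,
                      duration = duration, subject_id = subject_id,
                      trial_len = trial_len, truth = truth, config = config),
                 class = "recording_session")
  validate_session(s)
}

#' Validate a recording session
#'
#' Checks positive sampling rates, channel lengths consistent with the
#' stated duration (clock alignment), and sorted in-range stimulus onsets.
#'
#' @param session A `recording_session`.
#' @return The session, invisibly-checked; errors on violation.
#' @export
validate_session <- function(session) {
  with(session, {
    if (fs_hbt <= 0 || fs_raw <= 0 || fs_vel <= 0)
      stop("sampling rates must be positive")
    chk <- function(x, fs, name) {
      if (abs(length(x) / fs - duration) > 1 / fs + 1e-6)
        stop(sprintf("channel '%s' is misaligned with the session clock",
                     name))
    }
    chk(hbt, fs_hbt, "hbt"); chk(emg, fs_raw, "emg")
    chk(lfp, fs_raw, "lfp"); chk(velocity, fs_vel, "velocity")
    if (is.unsorted(stim_onsets, strictly = FALSE))
      stop("stimulus onsets must be sorted")
    if (length(stim_onsets) &&
        (min(stim_onsets) < 0 || max(stim_onsets) > duration))
      stop("stimulus onsets outside the session span")
  })
  session
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "Recording session '%s' (%s): %.0f s, %d stimuli\n",
    x$subject_id, x$age_group, x$duration, length(x$stim_onsets)))
  cat(sprintf("  hbt @ %g Hz, emg/lfp @ %g Hz, velocity @ %g Hz\n",
              x$fs_hbt, x$fs_raw, x$fs_vel))
  if (!is.null(x$truth)) cat("  generator ground truth attached\n")
  invisible(x)
}

#' Five-minute trial boundaries of a session
#'
#' @param session A `recording_session`.
#' @return Data frame with `start`, `end` (s).
#' @export
trial_bounds <- function(session) {
  n <- floor(session$duration / session$trial_len)
  if (n < 1L) return(data.frame(start = 0, end = session$duration))
  data.frame(start = (seq_len(n) - 1L) * session$trial_len,
             end = seq_len(n) * session$trial_len)
}

channel_files <- c(hbt = "hbt.csv", emg = "emg.csv", lfp = "lfp.csv",
                   velocity = "velocity.csv")

#' Write a session to a directory of plain-text files
#'
#' Channels as `time_s,value` CSV, stimulus onsets as CSV, metadata (and
#' ground truth, when present) as JSON, generator config as YAML.
#'
#' @param session A `recording_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs_of <- c(hbt = session$fs_hbt, emg = session$fs_raw,
             lfp = session$fs_raw, velocity = session$fs_vel)
  for (ch in names(channel_files)) {
    x <- session[[ch]]
    tt <- (seq_along(x) - 1L) / fs_of[[ch]]
    data.table::fwrite(data.table::data.table(time_s = tt, value = x),
                       file.path(dir, channel_files[[ch]]))
  }
  data.table::fwrite(data.table::data.table(onset_s = session$stim_onsets),
                     file.path(dir, "stim_onsets.csv"))
  meta <- list(subject_id = session$subject_id,
               age_group = session$age_group,
               duration = session$duration, fs_hbt = session$fs_hbt,
               fs_raw = session$fs_raw, fs_vel = session$fs_vel,
               trial_len = session$trial_len)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth)) {
    tr <- session$truth
    jsonlite::write_json(
      list(state_sequence = tr$state_sequence,
           hbt_offsets = as.list(tr$hbt_offsets),
           stim_outcomes = tr$stim_outcomes,
           duration = tr$duration, age_group = tr$age_group),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(session$config)) {
    cfg <- unclass(session$config)
    cfg$transition_matrix <- apply(cfg$transition_matrix, 1L, as.list,
                                   simplify = FALSE)
    cfg$evoked_template <- as.list(cfg$evoked_template)  # keep names in YAML
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Load a session written by [save_session()]
#'
#' @param dir Session directory.
#' @return A validated `recording_session` (ground truth restored when
#'   present).
#' @export
load_session <- function(dir) {
  need <- c(unname(channel_files), "stim_onsets.csv", "metadata.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing session file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  ch <- lapply(channel_files, function(f)
    data.table::fread(file.path(dir, f))$value)
  stims <- data.table::fread(file.path(dir, "stim_onsets.csv"))
  stims <- if (nrow(stims)) stims$onset_s else numeric(0)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    truth <- structure(
      list(state_sequence = as.data.frame(tr$state_sequence),
           hbt_offsets = unlist(tr$hbt_offsets),
           stim_outcomes = if (!is.null(tr$stim_outcomes) &&
                               length(tr$stim_outcomes))
             as.data.frame(tr$stim_outcomes) else NULL,
           duration = tr$duration, age_group = tr$age_group),
      class = "ground_truth")
  }
  recording_session(hbt = ch$hbt, fs_hbt = meta$fs_hbt, emg = ch$emg,
                    lfp = ch$lfp, fs_raw = meta$fs_raw,
                    velocity = ch$velocity, fs_vel = meta$fs_vel,
                    stim_onsets = stims, age_group = meta$age_group,
                    duration = meta$duration, subject_id = meta$subject_id,
                    trial_len = meta$trial_len, truth = truth)
}

#' Run the analysis pipeline on a session
#'
#' Executes the requested stages in dependency order: `score` (arousal
#' scoring), `spectra` (resting-state spectrum of the delta[HbT] trace),
#' `transitions` (qualified transitions + statistics; requires `score`),
#' `evoked` (stimulus-triggered averages split by pre-stimulus state;
#' requires `score`).  Either pass an existing `recording_session`, or a
#' [gen_config()] to simulate one first.
#'
#' @param x A `recording_session` or a `gen_config`.
#' @param stages Character vector of stages to run.
#' @param out_dir Optional directory; when given, a machine-readable
#'   `results.json` (with the resolved configuration and seed), hypnogram
#'   TSV and transition CSV are written there.
#' @return List with the session and one element per executed stage.
#' @export
run_pipeline <- function(x, stages = c("score", "spectra", "transitions",
                                       "evoked"),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(x, "gen_config")) {
    session <- simulate_session(x)
  } else if (inherits(x, "recording_session")) {
    session <- x
  } else stop("x must be a gen_config or recording_session")
  res <- list(session = session)
  needs_score <- intersect(c("transitions", "evoked"), stages)
  if (length(needs_score) && !("score" %in% stages))
    stop("stage(s) ", paste(needs_score, collapse = ", "),
         " require the 'score' stage")
  if ("score" %in% stages) {
    res$hypnogram <- score_session(session)
    res$bouts <- extract_bouts(res$hypnogram)
    res$fractions <- state_fractions(res$hypnogram)
  }
  if ("spectra" %in% stages) {
    rest <- rest_segments(session$velocity, session$fs_vel,
                          trial_bounds(session))
    res$rest_trials <- rest
    res$spectrum <- spectrum_fit(session$hbt, session$fs_hbt)
  }
  if ("transitions" %in% stages) {
    res$transitions <- find_transitions(res$hypnogram, session$hbt,
                                        session$fs_hbt)
    res$transition_stats <- transition_stats(res$transitions)
  }
  if ("evoked" %in% stages) {
    if (length(session$stim_onsets)) {
      lab <- split_stimuli_by_state(session$stim_onsets, res$hypnogram)
      res$evoked <- evoked_by_state(session$hbt, session$fs_hbt, lab)
      if (!is.null(res$evoked$pooled))
        res$evoked_metrics <- evoked_metrics(res$evoked$pooled)
    } else {
      res$evoked <- NULL
    }
  }
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  session <- res$session
  summary <- list(subject_id = session$subject_id,
                  age_group = session$age_group,
                  duration_s = session$duration,
                  n_stimuli = length(session$stim_onsets))
  if (!is.null(session$config)) summary$seed <- session$config$seed
  if (!is.null(res$fractions))
    summary$state_fraction <- as.list(res$fractions)
  if (!is.null(res$spectrum)) {
    summary$spectral <- list(beta = res$spectrum$beta, a = res$spectrum$a,
                             peak_freq_hz = res$spectrum$peak_freq,
                             peak_fraction = res$spectrum$peak_fraction)
  }
  if (!is.null(res$transition_stats) && nrow(res$transition_stats))
    summary$transitions <- res$transition_stats
  if (!is.null(res$evoked_metrics)) {
    m <- res$evoked_metrics
    summary$evoked <- list(peak_amp_uM = m$peak_amp,
                           time_to_peak_s = m$time_to_peak,
                           fwhm_s = m$fwhm, early_mean_uM = m$early_mean,
                           undershoot_mean_uM = m$undershoot_mean)
  }
  if (!is.null(session$config)) {
    cfg <- unclass(session$config)
    cfg$transition_matrix <- apply(cfg$transition_matrix, 1L, as.list,
                                   simplify = FALSE)
    summary$config <- cfg
  }
  jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  if (!is.null(res$hypnogram))
    utils::write.table(res$hypnogram, file.path(out_dir, "hypnogram.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$transitions) && nrow(res$transitions))
    utils::write.csv(res$transitions, file.path(out_dir, "transitions.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
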