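# Synthetic-session generator: semi-Markov arousal sequences with known
# ground truth, plus state-conditioned hemodynamic, EMG, LFP, locomotion and
# spiking channels.  All randomness is drawn from R's global RNG stream;
# simulate_session() seeds it once so a fixed seed reproduces every channel.

#' Build a generator configuration
#'
#' Assembles the full set of parameters used to synthesize a recording
#' session, starting from the per-age defaults of [age_defaults()].  Any
#' field can be overridden by name through `...` (e.g. `beta = 2`,
#' `hbt_noise_sigma = 0`, or a modified `state_params` table).
#'
#' @param age_group Age group: `"P15"`, `"P10"` or `"adult"`.
#' @param duration Session length in seconds.
#' @param fs_hbt Sampling rate of the hemodynamic channel (Hz; camera frame
#'   rate).
#' @param fs_raw Sampling rate of the raw EMG/LFP channels (Hz).  Must be at
#'   least twice the highest synthesized LFP frequency (100 Hz).
#' @param seed Integer seed; [simulate_session()] sets it before drawing.
#' @param stimulation Logical; schedule whisker stimuli for this session?
#' @param ... Named overrides of any default field.
#' @return An object of class `gen_config` (a named list).
#' @export
gen_config <- function(age_group = c("P15", "P10", "adult"), duration = 3600,
                       fs_hbt = 30, fs_raw = 1000, seed = 1L,
                       stimulation = FALSE, ...) {
  age_group <- match.arg(age_group)
  tab <- age_defaults(age_group)
  cfg <- list(
    age_group = age_group,
    duration = duration,
    fs_hbt = fs_hbt,
    fs_raw = fs_raw,
    fs_vel = fs_hbt,
    fs_mua = 20000,
    seed = as.integer(seed),
    stimulation = stimulation,
    states = tab$states,
    awake_states = tab$awake_states,
    sleep_states = tab$sleep_states,
    awaken_state = tab$awaken_state,
    state_params = tab$state_params,
    transition_matrix = tab$transition_matrix,
    initial_state = NULL,
    beta = tab$beta,
    hbt_noise_sigma = 3,
    vasomotion_freq = tab$vasomotion_freq,
    vasomotion_width = tab$vasomotion_width,
    vasomotion_amp = tab$vasomotion_amp,
    evoked_template = tab$evoked_template,
    baseline_rate = tab$baseline_rate,
    evoked_rate_gain = 2,
    p_awaken_given_sleep_stim = tab$p_awaken_given_sleep_stim,
    awaken_latency = 1,
    transition_tau = 3,
    isi_min = 60,
    isi_jitter = 20,
    stim_duration = 0.5,
    lfp_bands = list(delta = c(1, 4), theta = c(4, 10), gamma = c(40, 100)),
    lfp_noise_floor = 0.05,
    twitch_amp = 1.0,
    twitch_duration = 0.1,
    move_speed = 5,
    move_speed_sd = 1,
    velocity_noise_sd = 0.02)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown gen_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_gen_config(cfg)
  structure(cfg, class = "gen_config")
}

validate_gen_config <- function(cfg) {
  sp <- cfg$state_params
  if (!all(cfg$states %in% sp$state))
    stop("state_params must contain a row for every state")
  if (any(sp$emg_sigma < 0) || any(sp$twitch_rate < 0) ||
      any(sp$delta_gain < 0) || any(sp$theta_gain < 0) ||
      any(sp$gamma_gain < 0))
    stop("state gains, sigmas and twitch rates must be >= 0")
  if (any(sp$dwell_median <= 0)) stop("dwell_median must be > 0")
  if (any(!is.finite(sp$hbt_offset))) stop("hbt_offset must be finite")
  hi <- max(vapply(cfg$lfp_bands, max, numeric(1)))
  if (cfg$fs_raw < 2 * hi)
    stop("fs_raw must be at least twice the highest LFP band edge")
  p <- cfg$p_awaken_given_sleep_stim
  if (p < 0 || p > 1) stop("p_awaken_given_sleep_stim must be in [0, 1]")
  if (cfg$hbt_noise_sigma < 0 || cfg$vasomotion_amp < 0)
    stop("noise amplitudes must be >= 0")
  if (cfg$isi_min < cfg$stim_duration)
    stop("isi_min must exceed stim_duration")
  P <- cfg$transition_matrix
  if (!identical(dim(P), c(length(cfg$states), length(cfg$states))))
    stop("transition_matrix must be square over the state set")
  rs <- rowSums(P)
  if (any(rs > 0 & abs(rs - 1) > 1e-6))
    stop("transition_matrix rows must sum to 1 (or 0 for an absorbing state)")
  invisible(cfg)
}

# Stationary distribution of the embedded chain (absorbing rows allowed).
embedded_stationary <- function(P) {
  rs <- rowSums(P)
  Q <- P
  for (i in which(rs == 0)) Q[i, i] <- 1  # absorbing
  e <- eigen(t(Q))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# States reachable from `from` in the directed graph of P.
reachable_states <- function(P, from) {
  n <- nrow(P)
  seen <- logical(n)
  seen[from] <- TRUE
  repeat {
    new <- seen | (as.vector(seen %*% (P > 0)) > 0)
    if (all(new == seen)) break
    seen <- new
  }
  seen
}

#' Sample a semi-Markov arousal-state sequence
#'
#' Draws bout states from the embedded transition matrix and bout durations
#' from log-normal distributions parameterized by their median, then tiles
#' the session `[0, duration]` with the resulting intervals.  The final bout
#' is truncated at the session end.
#'
#' @param config A [gen_config()] object.
#' @return A `ground_truth` object: a list with `state_sequence` (data frame
#'   of `state`, `start`, `end`), the per-state `hbt_offsets`, and an empty
#'   `stim_outcomes` slot (filled by [apply_awakenings()]).
#' @export
sample_state_sequence <- function(config) {
  P <- config$transition_matrix
  states <- config$states
  pi_emb <- embedded_stationary(P)
  init <- config$initial_state
  if (is.null(init)) {
    init <- sample(states, 1L, prob = pi_emb)
  }
  s <- match(init, states)
  if (is.na(s)) stop("initial_state not in state set")
  reach <- reachable_states(P, s)
  # a state that participates in the graph (has outgoing edges) but can
  # never be entered from the initial state is a configuration error;
  # states with empty rows are treated as deliberately absorbing/unused
  active <- rowSums(P) > 0
  unreach <- states[active & !reach]
  if (length(unreach))
    stop("unreachable state in transition graph: ",
         paste(unreach, collapse = ", "))
  sp <- config$state_params
  med <- sp$dwell_median[match(states, sp$state)]
  sig <- sp$dwell_sigma[match(states, sp$state)]
  dur <- config$duration

  st <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- 0
  while (t < dur) {
    if (sum(P[s, ]) == 0) {           # absorbing state
      d <- dur - t
    } else {
      d <- stats::rlnorm(1, meanlog = log(med[s]), sdlog = sig[s])
    }
    end <- min(t + d, dur)
    st <- c(st, s); t0 <- c(t0, t); t1 <- c(t1, end)
    t <- end
    if (t >= dur) break
    s <- sample(seq_along(states), 1L, prob = P[s, ])
  }
  seq_tab <- data.frame(state = states[st], start = t0, end = t1,
                        stringsAsFactors = FALSE)
  truth <- list(state_sequence = seq_tab,
                hbt_offsets = stats::setNames(
                  sp$hbt_offset[match(states, sp$state)], states),
                stim_outcomes = NULL,
                duration = dur,
                age_group = config$age_group)
  class(truth) <- "ground_truth"
  truth
}

#' Schedule whisker-stimulus onsets
#'
#' Onsets are spaced by the minimum interstimulus interval plus uniform
#' jitter (so gaps are at least `isi_min` but non-degenerate, preventing
#' entrainment of slow oscillations).
#'
#' @param config A [gen_config()] object.
#' @return Numeric vector of onset times (s), possibly empty.
#' @export
schedule_stimuli <- function(config) {
  dur <- config$duration
  if (dur < config$isi_min) {
    t <- 10 + stats::runif(1, 0, config$isi_jitter)
    return(if (t + config$stim_duration <= dur) t else numeric(0))
  }
  onsets <- numeric(0)
  t <- 10 + stats::runif(1, 0, config$isi_jitter)
  while (t + config$stim_duration <= dur) {
    onsets <- c(onsets, t)
    t <- t + config$isi_min + stats::runif(1, 0, config$isi_jitter)
  }
  onsets
}

#' Insert stimulus-triggered awakenings into the ground truth
#'
#' Each stimulus delivered during sleep awakens the animal with probability
#' `p_awaken_given_sleep_stim`.  An awakening truncates the ongoing sleep
#' bout at onset + `awaken_latency` and restarts the semi-Markov chain from
#' the awake target state.  Pre-stimulus states and awakening outcomes are
#' recorded in `truth$stim_outcomes`.
#'
#' @param truth A `ground_truth` object.
#' @param onsets Stimulus onset times (s).
#' @param config The [gen_config()] used to generate `truth`.
#' @return The updated `ground_truth`.
#' @export
apply_awakenings <- function(truth, onsets, config) {
  if (length(onsets) == 0L) {
    truth$stim_outcomes <- data.frame(onset = numeric(0),
                                      pre_state = character(0),
                                      awakened = logical(0))
    return(truth)
  }
  P <- config$transition_matrix
  states <- config$states
  sp <- config$state_params
  med <- sp$dwell_median[match(states, sp$state)]
  sig <- sp$dwell_sigma[match(states, sp$state)]
  dur <- truth$duration
  tab <- truth$state_sequence
  out <- data.frame(onset = onsets, pre_state = NA_character_,
                    awakened = FALSE)
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    pre <- state_at(on, tab)
    out$pre_state[k] <- pre
    if (!(pre %in% config$sleep_states)) next
    t_wake <- on + config$awaken_latency
    if (t_wake >= dur) next
    if (state_at(t_wake, tab) %in% config$awake_states) next
    if (stats::runif(1) >= config$p_awaken_given_sleep_stim) next
    out$awakened[k] <- TRUE
    # truncate at t_wake and regrow the chain from the awake target state
    keep <- tab$start < t_wake
    tab <- tab[keep, , drop = FALSE]
    tab$end[nrow(tab)] <- t_wake
    s <- match(config$awaken_state, states)
    t <- t_wake
    while (t < dur) {
      d <- stats::rlnorm(1, meanlog = log(med[s]), sdlog = sig[s])
      end <- min(t + d, dur)
      tab <- rbind(tab, data.frame(state = states[s], start = t, end = end,
                                   stringsAsFactors = FALSE))
      t <- end
      if (t >= dur || sum(P[s, ]) == 0) break
      s <- sample(seq_along(states), 1L, prob = P[s, ])
    }
  }
  # merge consecutive bouts of identical state created by regrowth
  rl <- rle(tab$state)
  idx_end <- cumsum(rl$lengths)
  idx_start <- idx_end - rl$lengths + 1L
  tab <- data.frame(state = rl$values, start = tab$start[idx_start],
                    end = tab$end[idx_end], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  truth$state_sequence <- tab
  truth$stim_outcomes <- out
  truth
}

#' Synthesize 1/f^beta Gaussian noise
#'
#' Frequency-domain synthesis: Fourier amplitudes proportional to
#' `f^(-beta/2)` with independent random phases, floored below `f_floor`
#' (default the fundamental `fs/n`) so the variance stays finite, scaled to
#' the requested standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param beta Spectral exponent (`P ~ f^-beta`).
#' @param sigma Target standard deviation of the trace.
#' @param f_floor Frequency below which the spectrum is held flat (Hz).
#' @return Numeric vector of length `n`.
#' @export
synth_onef_noise <- function(n, fs, beta, sigma, f_floor = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(numeric(n))
  if (is.null(f_floor)) f_floor <- fs / n
  f <- (1:(n %/% 2L)) * fs / n
  x <- hermitian_noise(n, sqrt(pmax(f, f_floor)^(-beta)))
  x <- x - mean(x)
  x * (sigma / stats::sd(x))
}

# Gaussian noise with spectral amplitude `amp` at positive FFT frequencies,
# random phases, Hermitian symmetry (arbitrary overall scale).
hermitian_noise <- function(n, amp) {
  nf <- n %/% 2L
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  if (n %% 2L == 0L) {
    spec[nf] <- complex(real = amp[nf] * cos(ph[nf]))  # Nyquist is real
    full[2:(nf + 1L)] <- spec
    full[(nf + 2L):n] <- Conj(rev(spec[1:(nf - 1L)]))
  } else {
    full[2:(nf + 1L)] <- spec
    full[(nf + 2L):n] <- Conj(rev(spec))
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Synthesize a narrowband vasomotion component
#'
#' Band-limited Gaussian noise whose spectrum is a Gaussian bump centered at
#' `freq` with width `width`, scaled to RMS amplitude `amp` -- the
#' spontaneous ~0.1-0.3 Hz (adult) vascular oscillation that appears as a
#' peak in the pre-whitened resting spectrum.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param freq Center frequency (Hz).
#' @param width Spectral width (Hz).
#' @param amp RMS amplitude (uM).
#' @return Numeric vector of length `n`.
#' @export
synth_vasomotion <- function(n, fs, freq, width, amp) {
  if (amp < 0) stop("vasomotion amplitude must be >= 0")
  if (amp == 0) return(numeric(n))
  f <- (1:(n %/% 2L)) * fs / n
  shape <- exp(-(f - freq)^2 / (2 * width^2))
  if (sum(shape) == 0) return(numeric(n))
  x <- hermitian_noise(n, sqrt(shape))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (amp / s)
}

# Per-state parameter value at each time, as an unnamed numeric vector
# (memory-safe for multi-million-sample traces).
param_at <- function(times, seq_tab, values_by_state) {
  bi <- findInterval(times, seq_tab$start)
  bi[bi < 1L] <- 1L
  bi[bi > nrow(seq_tab)] <- nrow(seq_tab)
  unname(values_by_state[seq_tab$state])[bi]
}

# Per-sample state offset smoothed by exponential relaxation (time constant
# tau) toward the current state's offset.
smoothed_offsets <- function(truth, fs, tau) {
  n <- round(truth$duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  o <- param_at(tt, truth$state_sequence, truth$hbt_offsets)
  if (tau <= 0) return(o)
  a <- exp(-1 / (fs * tau))
  as.numeric(stats::filter(o * (1 - a), filter = a, method = "recursive",
                           init = o[1]))
}

#' Synthesize the hemodynamic (delta-HbT) channel
#'
#' The trace is the sum of (i) the per-state blood-volume offsets smoothed by
#' an exponential kernel with time constant `transition_tau`, (ii) `1/f^beta`
#' background noise, (iii) a narrowband vasomotion component, and (iv) a
#' gamma-variate evoked response for every stimulus delivered in an awake
#' state.  Stimuli that triggered awakening contribute no template; their
#' hemodynamic signature is the state transition already present in `truth`.
#'
#' @param truth A `ground_truth` (after [apply_awakenings()] if stimuli are
#'   present).
#' @param stims Stimulus onset times (s).
#' @param config A [gen_config()] object.
#' @return Numeric delta-HbT trace (uM) at `config$fs_hbt`.
#' @export
synth_hbt <- function(truth, stims = numeric(0), config) {
  fs <- config$fs_hbt
  n <- round(truth$duration * fs)
  x <- smoothed_offsets(truth, fs, config$transition_tau)
  x <- x + synth_onef_noise(n, fs, config$beta, config$hbt_noise_sigma)
  x <- x + synth_vasomotion(n, fs, config$vasomotion_freq,
                            config$vasomotion_width, config$vasomotion_amp)
  if (length(stims)) {
    tmpl <- config$evoked_template
    pre_states <- if (!is.null(truth$stim_outcomes) &&
                      nrow(truth$stim_outcomes)) {
      truth$stim_outcomes$pre_state[match(stims, truth$stim_outcomes$onset)]
    } else state_at(stims, truth$state_sequence)
    tt <- (seq_len(n) - 1L) / fs
    for (k in seq_along(stims)) {
      if (!(pre_states[k] %in% config$awake_states)) next
      x <- x + gamma_variate(tt - stims[k], peak_amp = tmpl[["peak_amp"]],
                             time_to_peak = tmpl[["time_to_peak"]],
                             fwhm = tmpl[["fwhm"]])
    }
  }
  x
}

#' Synthesize the nuchal EMG channel
#'
#' Gaussian noise whose standard deviation follows the per-state EMG tone,
#' with brief high-amplitude myoclonic twitches (Poisson process at the
#' per-state `twitch_rate`) during REM / active sleep.
#'
#' @inheritParams synth_hbt
#' @return Numeric raw EMG trace at `config$fs_raw`.
#' @export
synth_emg <- function(truth, config) {
  fs <- config$fs_raw
  n <- round(truth$duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  sp <- config$state_params
  sig_by_state <- stats::setNames(sp$emg_sigma, sp$state)
  sig <- param_at(tt, truth$state_sequence, sig_by_state)
  seq_tab <- truth$state_sequence
  rate_by_state <- stats::setNames(sp$twitch_rate, sp$state)
  for (i in seq_len(nrow(seq_tab))) {
    r <- rate_by_state[[seq_tab$state[i]]]
    if (r <= 0) next
    len <- seq_tab$end[i] - seq_tab$start[i]
    n_tw <- stats::rpois(1, r * len)
    if (n_tw == 0) next
    t_tw <- sort(stats::runif(n_tw, seq_tab$start[i], seq_tab$end[i]))
    for (t0 in t_tw) {
      idx <- win_idx(fs, t0, min(t0 + config$twitch_duration, seq_tab$end[i]),
                     n)
      sig[idx] <- pmax(sig[idx], config$twitch_amp)
    }
  }
  if (all(sig == 0)) return(numeric(n))
  stats::rnorm(n) * sig
}

#' Synthesize the hippocampal LFP channel
#'
#' Sum of band-limited Gaussian noise components (delta 1-4 Hz, theta
#' 4-10 Hz, gamma 40-100 Hz), each scaled per sample by the amplitude gain
#' of the ongoing arousal state, plus a small broadband floor.
#'
#' @inheritParams synth_hbt
#' @return Numeric raw LFP trace at `config$fs_raw`.
#' @export
synth_lfp <- function(truth, config) {
  fs <- config$fs_raw
  hi <- max(vapply(config$lfp_bands, max, numeric(1)))
  if (hi >= fs / 2) stop("LFP band edges must be below fs_raw/2")
  n <- round(truth$duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  sp <- config$state_params
  gain_cols <- c(delta = "delta_gain", theta = "theta_gain",
                 gamma = "gamma_gain")
  x <- numeric(n)
  for (b in names(config$lfp_bands)) {
    band <- config$lfp_bands[[b]]
    comp <- band_noise(n, fs, band[1], band[2])
    g <- param_at(tt, truth$state_sequence,
                  stats::setNames(sp[[gain_cols[[b]]]], sp$state))
    x <- x + comp * g
  }
  if (config$lfp_noise_floor > 0)
    x <- x + stats::rnorm(n, sd = config$lfp_noise_floor)
  x
}

# Unit-RMS Gaussian noise band-limited to [lo, hi] (frequency-domain).
band_noise <- function(n, fs, lo, hi) {
  f <- (1:(n %/% 2L)) * fs / n
  shape <- as.numeric(f >= lo & f <= hi)
  if (sum(shape) == 0) stop("empty band")
  x <- hermitian_noise(n, sqrt(shape))
  x / stats::sd(x)
}

#' Synthesize the treadmill velocity channel
#'
#' Locomotion occurs in 1-second epochs during states with nonzero
#' `locomotion_prob`; moving epochs have speed around `move_speed` and all
#' samples carry a small encoder noise floor.
#'
#' @inheritParams synth_hbt
#' @return Numeric velocity trace at `config$fs_vel`.
#' @export
synth_velocity <- function(truth, config) {
  fs <- config$fs_vel
  n <- round(truth$duration * fs)
  sp <- config$state_params
  n_sec <- ceiling(truth$duration)
  sec_t <- (seq_len(n_sec) - 1L) + 0.5
  p <- param_at(sec_t, truth$state_sequence,
                stats::setNames(sp$locomotion_prob, sp$state))
  moving_sec <- stats::runif(n_sec) < p
  speed_sec <- ifelse(moving_sec,
                      pmax(0.5, stats::rnorm(n_sec, config$move_speed,
                                             config$move_speed_sd)),
                      0)
  idx <- pmin(floor((seq_len(n) - 1L) / fs) + 1L, n_sec)
  v <- speed_sec[idx]
  v + stats::rnorm(n, sd = config$velocity_noise_sd)
}

#' Synthesize a multiunit spike train (and optional voltage trace)
#'
#' Inhomogeneous Poisson process at the configured baseline rate, elevated by
#' `evoked_rate_gain` during each stimulus pulse.  Optionally embeds biphasic
#' spike waveforms in Gaussian noise at `config$fs_mua` to exercise threshold
#' spike detection.
#'
#' @param stims Stimulus onset times (s).
#' @param config A [gen_config()] object.
#' @param duration Train duration (s); defaults to `config$duration`.
#' @param mua Logical; also return a voltage trace with embedded waveforms?
#' @return List with `times` (spike times, s) and, if `mua`, `voltage` and
#'   `fs` elements.
#' @export
synth_spikes <- function(stims = numeric(0), config, duration = NULL,
                         mua = FALSE) {
  if (is.null(duration)) duration <- config$duration
  r0 <- config$baseline_rate
  gain <- config$evoked_rate_gain
  rmax <- r0 * max(1, gain)
  times <- numeric(0)
  if (rmax > 0) {
    n_cand <- stats::rpois(1, rmax * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    in_stim <- rep(FALSE, length(cand))
    for (on in stims)
      in_stim <- in_stim | (cand >= on & cand < on + config$stim_duration)
    rate <- ifelse(in_stim, r0 * gain, r0)
    keep <- stats::runif(length(cand)) < rate / rmax
    times <- cand[keep]
  }
  out <- list(times = times)
  if (mua) {
    fs <- config$fs_mua
    n <- round(duration * fs)
    v <- stats::rnorm(n)
    # biphasic waveform, ~1 ms, peak 8 SD of the noise
    wlen <- round(0.001 * fs)
    wt <- seq_len(wlen) / fs
    wave <- 8 * sin(2 * pi * wt / 0.001) * exp(-wt / 0.0005)
    for (t0 in times) {
      i0 <- floor(t0 * fs) + 1L
      idx <- i0:min(i0 + wlen - 1L, n)
      v[idx] <- v[idx] + wave[seq_along(idx)]
    }
    out$voltage <- v
    out$fs <- fs
  }
  out
}

#' Simulate a complete recording session
#'
#' Seeds the RNG from `config$seed`, samples the arousal-state sequence,
#' schedules stimuli (if enabled), applies stimulus-triggered awakenings, and
#' synthesizes all channels.  Fixing the seed reproduces every channel
#' bit-identically.
#'
#' @param config A [gen_config()] object.
#' @return A `recording_session` object (see [recording_session()]) with the
#'   generator `ground_truth` attached as `$truth`.
#' @export
simulate_session <- function(config) {
  set.seed(config$seed)
  truth <- sample_state_sequence(config)
  stims <- if (isTRUE(config$stimulation)) schedule_stimuli(config)
           else numeric(0)
  truth <- apply_awakenings(truth, stims, config)
  hbt <- synth_hbt(truth, stims, config)
  emg <- synth_emg(truth, config)
  lfp <- synth_lfp(truth, config)
  vel <- synth_velocity(truth, config)
  recording_session(
    hbt = hbt, fs_hbt = config$fs_hbt,
    emg = emg, lfp = lfp, fs_raw = config$fs_raw,
    velocity = vel, fs_vel = config$fs_vel,
    stim_onsets = stims, age_group = config$age_group,
    duration = truth$duration,
    subject_id = sprintf("sim_%s_seed%d", config$age_group, config$seed),
    truth = truth, config = config)
}
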