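# Default parameter tables for the synthetic-session generator, one per age
# group.  Hemodynamic offsets, state fractions, bout-duration medians,
# power-law exponents, vasomotion frequencies, evoked-response templates and
# baseline multiunit rates encode the study conditions the analysis stages
# are expected to recover; EMG noise levels, LFP band gains and locomotion
# probabilities are chosen to give the well-separated per-state phenomenology
# (wake muscle tone vs. sleep atonia, NREM delta vs. REM theta/gamma,
# twitching during REM / active sleep) that rule-based scoring relies on.
#
# Embedded-chain transition probabilities are solved (see the methods
# vignette) so that the stationary time-in-state fractions of the semi-Markov
# model equal the target fractions given log-normal dwell times with the
# stated medians and log-sd 0.6.

.state_tab <- function(states, fraction, dwell_median, hbt_offset, emg_sigma,
                       twitch_rate, delta_gain, theta_gain, gamma_gain,
                       locomotion_prob, dwell_sigma = 0.6) {
  data.frame(state = states, fraction = fraction, dwell_median = dwell_median,
             dwell_sigma = dwell_sigma, hbt_offset = hbt_offset,
             emg_sigma = emg_sigma, twitch_rate = twitch_rate,
             delta_gain = delta_gain, theta_gain = theta_gain,
             gamma_gain = gamma_gain, locomotion_prob = locomotion_prob,
             stringsAsFactors = FALSE)
}

.tmat <- function(states, rows) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(states, states)
  m
}

.age_tables <- local({
  p15_states <- c("active_awake", "quiescent_awake", "NREM", "REM")
  p10_states <- c("active_awake", "quiescent_awake", "quiescent_asleep",
                  "active_asleep")
  list(
    P15 = list(
      states = p15_states,
      awake_states = p15_states[1:2],
      sleep_states = p15_states[3:4],
      awaken_state = "active_awake",
      state_params = .state_tab(
        p15_states,
        fraction     = c(27.78, 24.12, 39.90, 8.17) / 99.97,
        dwell_median = c(21, 17, 24, 34),
        hbt_offset   = c(-1.08, 0, 12.35, 25.18),
        emg_sigma    = c(1.0, 0.6, 0.10, 0.08),
        twitch_rate  = c(0, 0, 0, 0.5),
        delta_gain   = c(0.5, 0.7, 2.0, 0.4),
        theta_gain   = c(1.0, 0.6, 0.5, 2.0),
        gamma_gain   = c(1.0, 0.6, 0.4, 1.5),
        locomotion_prob = c(0.9, 0, 0, 0)),
      transition_matrix = .tmat(p15_states, list(
        c(0,        0.758397, 0.241603, 0),
        c(0.053473, 0,        0.946527, 0),
        c(0.605474, 0.25,     0,        0.144526),
        c(1,        0,        0,        0))),
      beta = 1.780, vasomotion_freq = 0.067, vasomotion_width = 0.010,
      vasomotion_amp = 0.8,
      evoked_template = c(peak_amp = 2.16, time_to_peak = 1.14, fwhm = 1.83),
      baseline_rate = 58.6,
      p_awaken_given_sleep_stim = 0.85),

    P10 = list(
      states = p10_states,
      awake_states = p10_states[1:2],
      sleep_states = p10_states[3:4],
      awaken_state = "active_awake",
      state_params = .state_tab(
        p10_states,
        fraction     = c(0.1500, 0.1281, 0.1500, 0.5719),
        dwell_median = c(19, 12, 19, 53),
        hbt_offset   = c(-6.0, 0, 9.9, 16.9),
        emg_sigma    = c(1.0, 0.6, 0.10, 0.08),
        twitch_rate  = c(0, 0, 0, 0.5),
        delta_gain   = c(0.6, 0.7, 1.0, 0.5),
        theta_gain   = c(0.8, 0.6, 0.5, 1.2),
        gamma_gain   = c(0.8, 0.6, 0.4, 1.0),
        locomotion_prob = c(0.9, 0, 0, 0)),
      transition_matrix = .tmat(p10_states, list(
        c(0,      0.6,    0,      0.4),
        c(0.2881, 0,      0.5879, 0.1240),
        c(0.2,    0,      0,      0.8),
        c(0.3001, 0.5499, 0.15,   0))),
      beta = 1.846, vasomotion_freq = 0.018, vasomotion_width = 0.003,
      vasomotion_amp = 1.5,
      evoked_template = c(peak_amp = 1.70, time_to_peak = 2.69, fwhm = 3.98),
      baseline_rate = 41.3,
      p_awaken_given_sleep_stim = 0.85),

    adult = list(
      states = p15_states,
      awake_states = p15_states[1:2],
      sleep_states = p15_states[3:4],
      awaken_state = "active_awake",
      state_params = .state_tab(
        p15_states,
        fraction     = c(0.30, 0.45, 0.20, 0.05),
        dwell_median = c(40, 60, 60, 45),
        hbt_offset   = c(-2, 0, 15, 30),
        emg_sigma    = c(1.0, 0.6, 0.10, 0.08),
        twitch_rate  = c(0, 0, 0, 0.5),
        delta_gain   = c(0.5, 0.7, 2.0, 0.4),
        theta_gain   = c(1.0, 0.6, 0.5, 2.0),
        gamma_gain   = c(1.0, 0.6, 0.4, 1.5),
        locomotion_prob = c(0.9, 0, 0, 0)),
      transition_matrix = .tmat(p15_states, list(
        c(0,        0.866548, 0.133452, 0),
        c(0.689028, 0,        0.310972, 0),
        c(0.366704, 0.3,      0,        0.333296),
        c(1,        0,        0,        0))),
      beta = 1.235, vasomotion_freq = 0.176, vasomotion_width = 0.020,
      vasomotion_amp = 1.0,
      evoked_template = c(peak_amp = 16.8, time_to_peak = 1.23, fwhm = 1.72),
      baseline_rate = 75.2,
      p_awaken_given_sleep_stim = 0.3)
  )
})

#' Default generator parameters for an age group
#'
#' Returns the built-in parameter table used by [gen_config()] for one of the
#' three age groups.  Postnatal-day-10 animals use a quiescent/active x
#' awake/asleep taxonomy; P15 and adult animals use active-awake,
#' quiescent-awake, NREM and REM.
#'
#' @param age_group One of `"P10"`, `"P15"`, `"adult"`.
#' @return A list with elements `states`, `awake_states`, `sleep_states`,
#'   `state_params` (per-state data frame), `transition_matrix`, spectral and
#'   evoked-template defaults.
#' @export
age_defaults <- function(age_group = c("P15", "P10", "adult")) {
  age_group <- match.arg(age_group)
  .age_tables[[age_group]]
}
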