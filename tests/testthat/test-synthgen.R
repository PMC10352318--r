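test_that("state sequences tile the session and respect the graph", {
  cfg <- gen_config("P15", duration = 2000, seed = 11)
  set.seed(cfg$seed)
  truth <- sample_state_sequence(cfg)
  tab <- truth$state_sequence
  expect_equal(tab$start[1], 0)
  expect_equal(tab$end[nrow(tab)], cfg$duration)
  expect_equal(tab$start[-1], tab$end[-nrow(tab)])      # no gaps or overlap
  expect_true(all(tab$state %in% cfg$states))
  # allowed-transition graph is honoured (REM exits only to active awake)
  P <- cfg$transition_matrix
  for (i in seq_len(nrow(tab) - 1L)) {
    expect_gt(P[tab$state[i], tab$state[i + 1L]], 0)
  }
})

test_that("an absorbing transition graph keeps the whole session in one state", {
  P <- matrix(0, 4, 4,
              dimnames = rep(list(age_defaults("P15")$states), 2))
  cfg <- gen_config("P15", duration = 500, seed = 1,
                    transition_matrix = P, initial_state = "NREM")
  set.seed(1)
  truth <- sample_state_sequence(cfg)
  expect_identical(unique(truth$state_sequence$state), "NREM")
  expect_equal(truth$state_sequence$end[nrow(truth$state_sequence)], 500)
})

test_that("a configured but unreachable state is a configuration error", {
  states <- age_defaults("P15")$states
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  # awake states oscillate; sleep states have outgoing edges but can never
  # be entered from the awake side
  P["active_awake", "quiescent_awake"] <- 1
  P["quiescent_awake", "active_awake"] <- 1
  P["NREM", "REM"] <- 1
  P["REM", "active_awake"] <- 1
  cfg <- gen_config("P15", duration = 100, seed = 1, transition_matrix = P,
                    initial_state = "active_awake")
  set.seed(1)
  expect_error(sample_state_sequence(cfg), "unreachable")
})

test_that("empirical state fractions converge to configured targets", {
  cfg <- gen_config("P15", duration = 1e5, seed = 0)
  target <- with(cfg$state_params, stats::setNames(fraction, state))
  for (seed in 1:3) {
    set.seed(seed)
    truth <- sample_state_sequence(cfg)
    tab <- truth$state_sequence
    frac <- tapply(tab$end - tab$start, tab$state, sum) / cfg$duration
    expect_true(all(abs(frac[names(target)] - target) < 0.015),
                label = sprintf("seed %d fractions within 1.5 pp", seed))
  }
})

test_that("bout durations follow the configured log-normal medians", {
  cfg <- gen_config("P15", duration = 1e5, seed = 4)
  set.seed(cfg$seed)
  truth <- sample_state_sequence(cfg)
  tab <- truth$state_sequence
  med_cfg <- with(cfg$state_params, stats::setNames(dwell_median, state))
  for (s in c("NREM", "active_awake")) {
    d <- (tab$end - tab$start)[tab$state == s]
    expect_gt(length(d), 100)
    expect_lt(abs(stats::median(d) - med_cfg[[s]]) / med_cfg[[s]], 0.20)
  }
})

test_that("stimulus schedules respect the minimum ISI and are jittered", {
  cfg <- gen_config("P15", duration = 3600, seed = 1, stimulation = TRUE)
  set.seed(1)
  on <- schedule_stimuli(cfg)
  expect_true(all(diff(on) >= cfg$isi_min))
  expect_true(all(on + cfg$stim_duration <= cfg$duration))
  short <- gen_config("P15", duration = 30, seed = 1)
  set.seed(1)
  expect_lte(length(schedule_stimuli(short)), 1L)
  # jitter: gap distribution is non-degenerate across seeds
  gaps <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    diff(schedule_stimuli(cfg))
  }))
  expect_gt(stats::var(gaps), 0)
})

test_that("noise-free HbT equals the exponentially relaxed state offsets", {
  truth <- manual_truth(c("quiescent_awake", "NREM"), c(60, 60),
                        c(quiescent_awake = 0, NREM = 12))
  cfg <- gen_config("P15", duration = 120, seed = 1, hbt_noise_sigma = 0,
                    vasomotion_amp = 0)
  x <- synth_hbt(truth, numeric(0), cfg)
  tt <- (seq_along(x) - 1) / cfg$fs_hbt
  # oracle: direct convolution solution of the relaxation toward the offset
  expect_equal(x[tt < 60], rep(0, sum(tt < 60)))
  post <- tt >= 60
  expect_equal(x[post], 12 * (1 - exp(-(tt[post] - 60 + 1 / cfg$fs_hbt) /
                                        cfg$transition_tau)),
               tolerance = 0.02)
  # constant state, all stochastic terms off -> constant trace at the offset
  truth1 <- manual_truth("NREM", 50, c(NREM = 12))
  x1 <- synth_hbt(truth1, numeric(0),
                  gen_config("P15", duration = 50, seed = 1,
                             hbt_noise_sigma = 0, vasomotion_amp = 0))
  expect_equal(x1, rep(12, length(x1)))
})

test_that("synthesized 1/f noise has the requested spectral exponent", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- synth_onef_noise(300 * 30, 30, beta = 2, sigma = 3)
    psd <- multitaper_psd(x, 30)
    b <- log_resample(psd$freq, psd$power)
    fit <- fit_power_law(b$freq, b$power)
    expect_lt(abs(fit$beta - 2), 0.15)
  }
})

test_that("awake-state stimuli carry the configured evoked template", {
  cfg <- gen_config("adult", duration = 1600, seed = 9,
                    hbt_noise_sigma = 0.5, vasomotion_amp = 0)
  truth <- manual_truth("quiescent_awake", 1600, c(quiescent_awake = 0),
                        age_group = "adult")
  stims <- seq(30, 1570, by = 70)
  set.seed(9)
  x <- synth_hbt(truth, stims, cfg)
  ea <- evoked_average(x, cfg$fs_hbt, stims)
  expect_gte(ea$n, 20)
  m <- evoked_metrics(ea)
  tmpl <- cfg$evoked_template
  expect_lt(abs(m$peak_amp - tmpl[["peak_amp"]]) / tmpl[["peak_amp"]], 0.1)
  expect_lt(abs(m$time_to_peak - tmpl[["time_to_peak"]]), 0.2)
})

test_that("EMG has state-dependent tone, twitches, and a silent zero mode", {
  # all-NREM truth is atonic relative to active awake
  cfg <- gen_config("P15", duration = 100, seed = 2)
  t_nrem <- manual_truth("NREM", 100, c(NREM = 12))
  t_awake <- manual_truth("active_awake", 100, c(active_awake = 0))
  set.seed(2)
  e_nrem <- synth_emg(t_nrem, cfg)
  set.seed(2)
  e_awake <- synth_emg(t_awake, cfg)
  expect_lt(mean(e_nrem^2), mean(e_awake^2))
  # Poisson twitch count in a REM segment: count clusters of samples that
  # reach twitch amplitude (background REM noise never gets near 0.4)
  t_rem <- manual_truth("REM", 400, c(REM = 25))
  counts <- vapply(1:5, function(s) {
    set.seed(s)
    e <- synth_emg(t_rem, cfg)
    tc <- which(abs(e) > 0.4) / cfg$fs_raw
    if (length(tc) == 0) return(0)
    sum(c(TRUE, diff(tc) > 0.05))
  }, numeric(1))
  lam <- 400 * 0.5
  expect_lt(abs(mean(counts) - lam) / lam, 0.2)
  # zero sigma and zero twitch rate -> identically zero trace
  sp <- cfg$state_params
  sp$emg_sigma <- 0
  sp$twitch_rate <- 0
  cfg0 <- gen_config("P15", duration = 20, seed = 1, state_params = sp)
  set.seed(1)
  expect_identical(synth_emg(manual_truth("NREM", 20, c(NREM = 0)), cfg0),
                   numeric(20 * cfg0$fs_raw))
})

test_that("LFP band content is state dependent", {
  cfg <- gen_config("P15", duration = 200, seed = 3)
  bp <- function(x, band) mean(band_power_trace(x, cfg$fs_raw, band))
  set.seed(3)
  nrem <- synth_lfp(manual_truth("NREM", 200, c(NREM = 12)), cfg)
  expect_gt(bp(nrem, c(1, 4)), bp(nrem, c(4, 10)))
  set.seed(3)
  rem <- synth_lfp(manual_truth("REM", 200, c(REM = 25)), cfg)
  expect_gt(bp(rem, c(4, 10)) / bp(rem, c(1, 4)), 1)
})

test_that("spike trains follow the configured rates", {
  cfg <- gen_config("P10", duration = 100, seed = 5)
  set.seed(5)
  tr <- synth_spikes(numeric(0), cfg, duration = 100)
  lam <- 100 * cfg$baseline_rate  # 4130 expected at the P10 baseline rate
  expect_lt(abs(length(tr$times) - lam), 4 * sqrt(lam))
  # rate 0 -> empty train
  cfg0 <- gen_config("P10", duration = 10, seed = 5, baseline_rate = 0)
  set.seed(5)
  expect_length(synth_spikes(numeric(0), cfg0, duration = 10)$times, 0)
  # evoked gain 2 doubles the PSTH during the stimulus
  cfgs <- gen_config("P15", duration = 3600, seed = 6)
  stims <- seq(30, 3570, by = 60)
  set.seed(6)
  tr2 <- synth_spikes(stims, cfgs, duration = 3600)
  in_stim <- function(t) any(t >= stims & t < stims + cfgs$stim_duration)
  n_in <- sum(vapply(tr2$times, in_stim, logical(1)))
  t_in <- length(stims) * cfgs$stim_duration
  t_out <- 3600 - t_in
  ratio <- (n_in / t_in) / ((length(tr2$times) - n_in) / t_out)
  expect_lt(abs(ratio - 2), 0.3)
})

test_that("a fixed seed reproduces the whole session bit-identically", {
  cfg <- gen_config("P15", duration = 150, seed = 77, stimulation = TRUE)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$hbt, s2$hbt)
  expect_identical(s1$emg, s2$emg)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$velocity, s2$velocity)
  expect_identical(s1$stim_onsets, s2$stim_onsets)
  expect_identical(s1$truth$state_sequence, s2$truth$state_sequence)
})

test_that("stimuli during sleep can awaken the animal with the set probability", {
  cfg <- gen_config("P15", duration = 4000, seed = 8, stimulation = TRUE,
                    p_awaken_given_sleep_stim = 1)
  ses <- simulate_session(cfg)
  out <- ses$truth$stim_outcomes
  asleep <- out$pre_state %in% cfg$sleep_states
  # with p = 1 every sleep stimulus (still asleep at the latency) awakens
  expect_gt(sum(asleep), 5)
  expect_gt(mean(out$awakened[asleep]), 0.8)
  expect_false(any(out$awakened[!asleep]))
  # awakening inserts an awake bout right after the latency
  tr <- ses$truth
  for (on in out$onset[out$awakened][1:3]) {
    st <- tr$state_sequence
    i <- findInterval(on + cfg$awaken_latency + 0.01, st$start)
    expect_identical(st$state[i], cfg$awaken_state)
  }
})
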