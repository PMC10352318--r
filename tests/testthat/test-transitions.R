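hyp_from_labels <- function(lab, bin = 5, age_group = "P15") {
  structure(
    data.frame(bin_start = (seq_along(lab) - 1) * bin,
               bin_end = seq_along(lab) * bin, label = lab,
               stringsAsFactors = FALSE),
    class = c("hypnogram", "data.frame"), bin = bin, age_group = age_group,
    states = age_defaults(age_group)$states)
}

test_that("transition qualification enforces the 15 s / 15 s rule", {
  fs <- 10
  # one 20 s -> 20 s boundary qualifies
  hyp <- hyp_from_labels(c(rep("NREM", 4), rep("active_awake", 4)))
  hbt <- rep(0, 40 * fs)
  ev <- find_transitions(hyp, hbt, fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t, 20)
  expect_equal(ev$from, "NREM")
  expect_equal(ev$to, "active_awake")
  # a 10-s preceding bout is excluded
  hyp2 <- hyp_from_labels(c(rep("REM", 3), rep("NREM", 2),
                            rep("active_awake", 5)))
  ev2 <- find_transitions(hyp2, rep(0, 50 * fs), fs)
  expect_equal(nrow(ev2), 0)
  # windows must fit inside the recording
  hyp3 <- hyp_from_labels(c(rep("NREM", 3), rep("active_awake", 3)))
  ev3 <- find_transitions(hyp3, rep(0, 30 * fs), fs)  # t = 15, t-15 = 0 ok
  expect_equal(nrow(ev3), 1)
  hyp4 <- hyp_from_labels(c(rep("NREM", 3), rep("active_awake", 3)))
  ev4 <- find_transitions(hyp4, rep(0, 29 * fs), fs)  # t+15 beyond end
  expect_equal(nrow(ev4), 0)
})

test_that("an ideal offset step yields the exact configured delta", {
  fs <- 30
  hyp <- hyp_from_labels(c(rep("NREM", 6), rep("active_awake", 6)))
  t0 <- 30
  tt <- (seq_len(60 * fs) - 1) / fs
  hbt <- ifelse(tt < t0, 12.35, 12.35 - 13.43)
  ev <- find_transitions(hyp, hbt, fs)
  expect_equal(ev$delta, -13.43)
  expect_equal(ev$baseline_mean, 12.35)
  # oracle: brute-force two-window mean difference on arbitrary noise
  set.seed(41)
  x <- stats::rnorm(60 * fs)
  evx <- find_transitions(hyp, x, fs)
  base <- mean(x[tt >= t0 - 15 & tt < t0 - 5])
  resp <- mean(x[tt >= t0 + 5 & tt < t0 + 15])
  expect_equal(evx$delta, resp - base, tolerance = 1e-12)
})

test_that("per-type statistics aggregate deltas with flags for singletons", {
  ev <- data.frame(from = c("a", "a", "a", "b"), to = c("w", "w", "w", "w"),
                   t = 1:4, baseline_mean = 0, response_mean = 0,
                   delta = c(-10, -14, -16.29, 3))
  st <- transition_stats(ev)
  aw <- st[st$from == "a", ]
  expect_equal(aw$mean_delta, mean(c(-10, -14, -16.29)))
  expect_equal(aw$sd_delta, stats::sd(c(-10, -14, -16.29)))
  bw <- st[st$from == "b", ]
  expect_true(bw$single_event)
  expect_true(is.na(bw$sd_delta))
})

test_that("transition deltas recover generator offsets on synthetic sessions", {
  evs <- do.call(rbind, lapply(c(101, 102), function(seed) {
    ses <- p15_session(seed)
    find_transitions(scored_hypnogram(ses), ses$hbt, ses$fs_hbt)
  }))
  st <- transition_stats(evs)
  off <- age_defaults("P15")$state_params
  offv <- stats::setNames(off$hbt_offset, off$state)
  # every well-sampled type recovers its configured offset difference
  for (i in which(st$n >= 10)) {
    target <- offv[[st$to[i]]] - offv[[st$from[i]]]
    expect_lt(abs(st$mean_delta[i] - target), 3,
              label = sprintf("%s->%s delta %.2f vs %.2f", st$from[i],
                              st$to[i], st$mean_delta[i], target))
  }
  # sign convention: sleep->wake transitions are negative
  s2w <- st$from %in% c("NREM", "REM") &
    st$to %in% c("active_awake", "quiescent_awake") & st$n >= 5
  expect_true(all(st$mean_delta[s2w] < 0))
})

test_that("peri-transition averages align events and flag empty sets", {
  fs <- 10
  hyp <- hyp_from_labels(rep(c(rep("NREM", 5), rep("active_awake", 5)), 4))
  tt <- (seq_len(200 * fs) - 1) / fs
  x <- sin(2 * pi * tt / 50)  # periodic, so all events are identical
  ev <- find_transitions(hyp, x, fs)
  pta <- peri_transition_average(x, fs, ev, "NREM", "active_awake",
                                 window = 10)
  expect_gt(pta$n, 1)
  expect_equal(pta$sd, rep(0, length(pta$sd)), tolerance = 1e-12)
  none <- peri_transition_average(x, fs, ev, "REM", "NREM", window = 10)
  expect_true(none$empty)
  expect_equal(none$n, 0)
})

test_that("stimuli are labeled by the bin preceding their onset", {
  hyp <- hyp_from_labels(c("NREM", "NREM", "active_awake", "active_awake"))
  # onset 2 s into an awake bin that follows a NREM bin -> labeled NREM
  lab <- split_stimuli_by_state(12, hyp)
  expect_equal(lab$state, "NREM")
  # all-awake hypnogram labels everything awake
  hyp2 <- hyp_from_labels(rep("quiescent_awake", 6))
  lab2 <- split_stimuli_by_state(c(7, 14, 22), hyp2)
  expect_true(all(lab2$state == "quiescent_awake"))
  # an onset in the first bin has no preceding bin and is excluded
  lab3 <- split_stimuli_by_state(c(2, 12), hyp)
  expect_equal(nrow(lab3), 1)
  expect_equal(attr(lab3, "n_excluded"), 1)
})

test_that("stimulus labels agree with generator pre-states", {
  cfg <- gen_config("P15", duration = 2500, seed = 71, stimulation = TRUE)
  ses <- cached("p15stim_71", simulate_session(cfg))
  tru_hyp <- truth_hypnogram(ses$truth)
  lab <- split_stimuli_by_state(ses$stim_onsets, tru_hyp)
  out <- ses$truth$stim_outcomes
  m <- merge(lab, out, by = "onset")
  # exclude stimuli within 5 s of a truth transition, where the bin-before
  # label and the instantaneous state legitimately differ
  tab <- ses$truth$state_sequence
  near <- vapply(m$onset, function(on)
    any(abs(tab$start - on) < 5), logical(1))
  expect_true(all(m$state[!near] == m$pre_state[!near]))
})

test_that("state-split evoked averages satisfy the pooled weighted identity", {
  fs <- 25
  set.seed(43)
  x <- stats::rnorm(3000 * fs)
  lab <- data.frame(onset = seq(40, 2900, by = 75),
                    state = rep(c("quiescent_awake", "NREM"), length.out = 39))
  ebs <- evoked_by_state(x, fs, lab, pre_s = 5, post_s = 15)
  expect_setequal(names(ebs$by_state), c("quiescent_awake", "NREM"))
  nq <- ebs$by_state$quiescent_awake$n
  nn <- ebs$by_state$NREM$n
  pooled_expect <- (nq * ebs$by_state$quiescent_awake$mean +
                      nn * ebs$by_state$NREM$mean) / (nq + nn)
  expect_equal(ebs$pooled$mean, pooled_expect, tolerance = 1e-12)
  expect_equal(ebs$pooled$n, nq + nn)
  # a state with fewer than min_n stimuli is reported as excluded
  lab2 <- rbind(lab, data.frame(onset = 1000.2, state = "REM"))
  ebs2 <- evoked_by_state(x, fs, lab2, pre_s = 5, post_s = 15)
  expect_true("REM" %in% ebs2$excluded)
  # one state only: pooled equals that state's average
  lab3 <- lab[lab$state == "NREM", ]
  ebs3 <- evoked_by_state(x, fs, lab3, pre_s = 5, post_s = 15)
  expect_equal(ebs3$pooled$mean, ebs3$by_state$NREM$mean)
})

test_that("awake stimuli dilate while sleep stimuli constrict on synthetic data", {
  ses <- cached("p15stim_71",
                simulate_session(gen_config("P15", duration = 2500,
                                            seed = 71,
                                            stimulation = TRUE)))
  hyp <- cached("p15stim_71_hyp", score_session(ses))
  lab <- split_stimuli_by_state(ses$stim_onsets, hyp)
  lab$state <- ifelse(lab$state %in% c("active_awake", "quiescent_awake"),
                      "awake", lab$state)
  ebs <- evoked_by_state(ses$hbt, ses$fs_hbt, lab)
  expect_true("awake" %in% names(ebs$by_state))
  awk <- ebs$by_state$awake
  post_early <- awk$time >= 0 & awk$time < 3
  expect_gt(max(awk$mean[post_early]), 0)
  if ("NREM" %in% names(ebs$by_state)) {
    nrem <- ebs$by_state$NREM
    late <- nrem$time >= 5 & nrem$time < 15
    # stimulation in NREM triggers awakening: late constriction
    expect_lt(mean(nrem$mean[late]), 0)
  }
})

test_that("peri-stimulus awake probability is complementary and rises", {
  # all-awake hypnogram: P(awake) = 1 at every offset
  hyp <- hyp_from_labels(rep("active_awake", 40))
  pp <- peristim_awake_probability(hyp, c(60, 100, 140), window = 30)
  expect_true(all(pp$p_awake == 1))
  expect_equal(pp$p_awake + pp$p_asleep, rep(1, nrow(pp)))
  # synthetic stimulated session: probability rises after the stimulus by
  # about p_awaken * P(asleep before)
  ses <- cached("p15stim_71",
                simulate_session(gen_config("P15", duration = 2500,
                                            seed = 71,
                                            stimulation = TRUE)))
  hyp2 <- cached("p15stim_71_hyp", score_session(ses))
  pp2 <- peristim_awake_probability(hyp2, ses$stim_onsets, window = 30)
  expect_equal(pp2$p_awake + pp2$p_asleep, rep(1, nrow(pp2)))
  pre <- mean(pp2$p_awake[pp2$peri_time < -5])
  post <- max(pp2$p_awake[pp2$peri_time >= 0 & pp2$peri_time <= 15])
  p_aw <- 0.85
  expect_gt(post, pre + 0.5 * (1 - pre) * p_aw)
})
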