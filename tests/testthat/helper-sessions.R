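# Shared fixtures: simulated sessions are expensive, so they are built once
# per test run and memoized across test files.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, force(expr), envir = .session_cache)
  get(key, envir = .session_cache)
}

p15_session <- function(seed = 101, duration = 3000) {
  cached(sprintf("p15_%d_%d", seed, duration),
         simulate_session(gen_config("P15", duration = duration,
                                     seed = seed)))
}

p10_session <- function(seed = 201, duration = 3000) {
  cached(sprintf("p10_%d_%d", seed, duration),
         simulate_session(gen_config("P10", duration = duration,
                                     seed = seed)))
}

adult_stim_session <- function(seed = 301, duration = 2400) {
  cached(sprintf("adultstim_%d_%d", seed, duration),
         simulate_session(gen_config("adult", duration = duration,
                                     seed = seed, stimulation = TRUE)))
}

scored_hypnogram <- function(session) {
  cached(paste0("hyp_", session$subject_id, "_", session$duration),
         score_session(session))
}

# A deterministic ground truth with hand-chosen bouts (for window tests).
manual_truth <- function(states, durations, offsets, age_group = "P15") {
  ends <- cumsum(durations)
  structure(list(
    state_sequence = data.frame(state = states,
                                start = c(0, ends[-length(ends)]),
                                end = ends, stringsAsFactors = FALSE),
    hbt_offsets = offsets,
    stim_outcomes = NULL,
    duration = ends[length(ends)],
    age_group = age_group), class = "ground_truth")
}
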