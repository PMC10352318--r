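# Heavy study-scale fixtures shared by the parameter-recovery tests:
# three 10,000-s sessions per age at the default study conditions.

study_sessions <- function(age, seeds = 1:3, duration = 10000,
                           stimulation = FALSE) {
  lapply(seeds, function(s) {
    key <- sprintf("study_%s_%d_%d_%d", age, s, duration, stimulation)
    cached(key, {
      ses <- simulate_session(gen_config(age, duration = duration, seed = s,
                                         stimulation = stimulation))
      list(session = ses, hypnogram = score_session(ses))
    })
  })
}

study_transition_events <- function() {
  cached("study_p15_events", {
    do.call(rbind, lapply(study_sessions("P15"), function(x) {
      find_transitions(x$hypnogram, x$session$hbt, x$session$fs_hbt)
    }))
  })
}
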