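# Shared fixtures: built once per test run, all seeded.

moderate_session <- function(seed = 42, n_cycles = 15, ...) {
  simulate_session(gait_model_params(...), injury_params("moderate"),
                   n_cycles = n_cycles, seed = seed)
}

intact_session <- function(seed = 8, n_cycles = 15, ...) {
  simulate_session(gait_model_params(...), injury_params("intact"),
                   n_cycles = n_cycles, seed = seed)
}

# programmed truth events as per-limb gait_events lists
split_truth <- function(session) {
  lapply(c(left = "left", right = "right"), function(l) {
    ev <- session$events_truth[session$events_truth$limb == l,
                               c("time_s", "event")]
    ev <- ev[order(ev$time_s), ]
    rownames(ev) <- NULL
    class(ev) <- c("gait_events", "data.frame")
    ev
  })
}

# per-limb cycles from the programmed truth events
truth_cycles <- function(session, limb) {
  ev <- session$events_truth
  ev <- ev[ev$limb == limb, c("time_s", "event")]
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  segment_cycles(ev, limb = limb)
}

# detected-event offsets (s) relative to the programmed truth
event_offsets <- function(session, limb, foot = "mtp5") {
  kin <- session$kinematics
  fs <- session$timeline$params$frame_rate
  ev <- detect_gait_events(kin[[paste0(limb, "_", foot, "_y_cm")]], fs,
                           time_s = kin$time_s)
  tru <- session$events_truth[session$events_truth$limb == limb, ]
  vapply(seq_len(nrow(ev)), function(i) {
    d <- ev$time_s[i] - tru$time_s[tru$event == ev$event[i]]
    d[which.min(abs(d))]
  }, numeric(1))
}

# iMG burst metrics (duration, activation) from truth cycles
img_metrics <- function(session) {
  m <- compute_emg_metrics(session, truth_cycles(session, "left"),
                           truth_cycles(session, "right"))
  m[m$muscle == "iMG", ]
}
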