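test_that("timelines are deterministic and strictly alternating per limb", {
  p <- gait_model_params()
  inj <- injury_params("moderate")
  a <- generate_gait_timeline(p, inj, 10, seed = 5)
  b <- generate_gait_timeline(p, inj, 10, seed = 5)
  expect_identical(a$events, b$events)
  for (limb in c("left", "right")) {
    ev <- a$events[a$events$limb == limb, ]
    ev <- ev[order(ev$time_s), ]
    expect_true(all(diff(ev$time_s) > 0))
    expect_true(all(ev$event[-1] != ev$event[-nrow(ev)]))
  }
  expect_error(generate_gait_timeline(p, inj, 0), "n_cycles")
})

test_that("intact timelines are symmetric; injured ones carry the programmed dominance", {
  p <- gait_model_params(cycle_jitter = 0)
  tl0 <- generate_gait_timeline(p, injury_params("intact"), 8, seed = 1)
  expect_equal(mean(tl0$cycles$swing_left), mean(tl0$cycles$swing_right),
               tolerance = 1e-12)
  tl <- generate_gait_timeline(p, injury_params("moderate"), 8, seed = 1)
  expect_equal(mean(tl$cycles$swing_left) / mean(tl$cycles$swing_right) - 1,
               0.29, tolerance = 1e-10)
  expect_equal(mean(tl$cycles$stance_right) / mean(tl$cycles$stance_left) - 1,
               0.16, tolerance = 1e-10)
})

test_that("the analysis pipeline recovers the programmed swing dominance", {
  s <- moderate_session()
  a <- session_asymmetry(compute_cycle_metrics(s))
  expect_lt(abs(a$swing - 0.29), 0.03)
})

test_that("sessions are bit-identical under a fixed seed", {
  s1 <- moderate_session(seed = 7)
  s2 <- moderate_session(seed = 7)
  expect_identical(s1$kinematics, s2$kinematics)
  expect_identical(s1$emg, s2$emg)
  expect_identical(s1$events_truth, s2$events_truth)
})

test_that("kinematic generator truths round-trip through the metrics", {
  # noiseless: exact step height and posture
  s0 <- simulate_session(gait_model_params(noise_sd_kin = 0, cycle_jitter = 0),
                         injury_params("intact"), n_cycles = 8, seed = 2)
  cm0 <- compute_cycle_metrics(s0, events = split_truth(s0))
  expect_lt(abs(mean(cm0$step_height_cm[cm0$limb == "right"]) - 2.0), 0.05)
  expect_equal(unique(round(cm0$posture_cm[cm0$limb == "left"], 10)), 5.0)
  # default noise: programmed right step height within 10%
  s <- moderate_session()
  cm <- compute_cycle_metrics(s)
  expect_lt(abs(mean(cm$step_height_cm[cm$limb == "right"]) - 2.0), 0.2)
  # crest drop 1 cm from 5 cm -> 80% of baseline
  pct <- mean(cm$posture_cm[cm$limb == "left"]) / 5 * 100
  expect_lt(abs(pct - 80), 2)
  # drag fraction
  expect_lt(abs(mean(cm$drag_index[cm$limb == "left"]) - 0.3), 0.05)
})

test_that("full dragging keeps the toe at ground for the whole swing", {
  s <- simulate_session(gait_model_params(noise_sd_kin = 0),
                        injury_params("moderate", drag_fraction = 1),
                        n_cycles = 6, seed = 3)
  cm <- compute_cycle_metrics(s, events = split_truth(s))
  expect_equal(cm$drag_index[cm$limb == "left"],
               rep(1, sum(cm$limb == "left")))
})

test_that("EMG envelopes are non-negative, seeded, and burst-scaled by injury", {
  s <- moderate_session(seed = 4)
  for (m in emg_muscles()) expect_true(all(s$emg[[m]] >= 0))
  s2 <- moderate_session(seed = 4)
  expect_identical(s$emg, s2$emg)

  base <- intact_session()
  inj <- moderate_session()
  mb <- img_metrics(base); mi <- img_metrics(inj)
  dur_ratio <- mean(mi$burst_duration_s, na.rm = TRUE) /
    mean(mb$burst_duration_s, na.rm = TRUE)
  act_ratio <- mean(mi$total_activation_mVs, na.rm = TRUE) /
    mean(mb$total_activation_mVs, na.rm = TRUE)
  expect_lt(abs(dur_ratio - 0.28), 0.03)   # -72% burst duration
  expect_lt(abs(act_ratio - 0.08), 0.02)   # -92% total activation
})

test_that("zero burst amplitudes yield no detectable bursts", {
  p <- emg_model_params(burst_amplitude = c(iTA = 0, cTA = 0, iMG = 0,
                                            cMG = 0),
                        noise_sd_emg = 0)
  s <- simulate_session(emg_params = p, n_cycles = 5, seed = 1)
  expect_equal(nrow(detect_bursts(s$emg$iTA, time_s = s$emg$time_s)), 0)
})

test_that("stimulation effects obey the zero-effect boundaries", {
  s <- moderate_session(seed = 6)
  model <- stim_effect_model()
  rl <- s$timeline$events$time_s[s$timeline$events$limb == "right" &
                                   s$timeline$events$event == "lift"]
  # at amp_min: no effect at all
  st_min <- data.frame(onset_s = rl[3], amplitude_uA = model$amp_min)
  s_min <- apply_stimulation_effects(s, st_min, model)
  expect_identical(s_min$kinematics, s$kinematics)
  expect_identical(s_min$emg, s$emg)
  # far outside the kernel: no effect either
  st_far <- data.frame(onset_s = rl[3] + 0.3, amplitude_uA = model$amp_max)
  s_far <- apply_stimulation_effects(s, st_far, model)
  expect_identical(s_far$kinematics, s$kinematics)
  # above amp_max: rejected
  expect_error(apply_stimulation_effects(
    s, data.frame(onset_s = rl[3], amplitude_uA = model$amp_max + 1), model),
    "amplitudes")
})

test_that("the phase kernel is 1 inside the coherence window and 0 far outside", {
  expect_equal(phase_kernel(c(-0.075, 0, 0.075)), c(1, 1, 1))
  expect_equal(phase_kernel(c(-0.2, 0.151)), c(0, 0))
  mid <- phase_kernel(0.1125)  # halfway through the decay flank
  expect_gt(mid, 0); expect_lt(mid, 1)
})

test_that("dose-response gain is recovered from kernel-centre trains", {
  s0 <- moderate_session(seed = 13)
  model <- stim_effect_model()
  rl <- s0$timeline$events$time_s[s0$timeline$events$limb == "right" &
                                    s0$timeline$events$event == "lift"]
  amps <- amplitude_sweep(model$amp_min, model$amp_max, 4)
  means <- vapply(amps, function(A) {
    st <- data.frame(onset_s = rl[2:11], amplitude_uA = A)
    sA <- apply_stimulation_effects(s0, st, model)
    cm <- compute_cycle_metrics(sA, events = split_truth(sA))
    mean(cm$step_height_cm[cm$limb == "right" & cm$cycle %in% 2:11])
  }, numeric(1))
  fit <- linear_fit_vaf(amps, means)
  gain_hat <- fit$slope / (fit$intercept + fit$slope * model$amp_min)
  expect_equal(gain_hat, model$gain_step_height, tolerance = 0.1)
  expect_gt(fit$vaf, 99)
})

test_that("motor-map truths follow the scenario multipliers and are seeded", {
  lay <- electrode_layout()
  expect_equal(lay$n_sites, 32L)
  m1 <- generate_motor_map_truth(lay, "intact", seed = 3)
  m2 <- generate_motor_map_truth(lay, "intact", seed = 3)
  expect_identical(m1, m2)
  f_int <- map_size(m1, "ipsi")$fraction
  d5 <- generate_motor_map_truth(lay, "day5", seed = 3)
  f_d5 <- map_size(d5, "ipsi")$fraction
  # day-5 ipsilateral transmission: ~10% of intact (one site on this grid)
  expect_equal(f_d5 * lay$n_sites, round(0.10 * f_int * lay$n_sites),
               tolerance = 1e-12)
  expect_error(generate_motor_map_truth(lay, "day99"), "unknown scenario")
  # category "none" iff threshold absent
  expect_true(all(is.na(d5$threshold_uA) == (d5$category == "none")))
})

test_that("rhythm generator produces the condition-specific responses", {
  r <- generate_rhythm_response("intact", seed = 2, n_repetitions = 3)
  res <- classify_rhythm(r$emg, train_onset_s = r$train$onset)
  expect_equal(res$classification, "bilateral_alternated")
  expect_equal(res$n_repetitions, 3L)

  rk <- generate_rhythm_response("ketamine", seed = 2)
  expect_equal(classify_rhythm(rk$emg, rk$train$onset)$classification, "none")

  rs <- generate_rhythm_response("sci_severe_wk1", seed = 2,
                                 n_repetitions = 2)
  expect_equal(classify_rhythm(rs$emg, rs$train$onset)$classification,
               "unilateral")
})
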