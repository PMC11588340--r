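test_that("noiseless sessions give events within one frame of truth", {
  s <- simulate_session(gait_model_params(noise_sd_kin = 0),
                        injury_params("moderate"), n_cycles = 12, seed = 5)
  frame <- 1 / s$timeline$params$frame_rate
  for (limb in c("left", "right")) {
    expect_lt(max(abs(event_offsets(s, limb))), frame)
  }
})

test_that("default-noise sessions keep >=95% of events within two frames", {
  off <- c(event_offsets(moderate_session(seed = 11), "left"),
           event_offsets(moderate_session(seed = 11), "right"),
           event_offsets(moderate_session(seed = 12), "left"),
           event_offsets(moderate_session(seed = 12), "right"))
  frame <- 1 / 119.2
  expect_gte(mean(abs(off) <= 2 * frame), 0.95)
})

test_that("degenerate trajectories yield no events", {
  expect_equal(nrow(detect_gait_events(rep(1, 500), 119.2)), 0)
  expect_equal(nrow(detect_gait_events(rep(1, 3), 119.2)), 0)
})

test_that("cycle segmentation counts triples and drops partial cycles", {
  s <- simulate_session(n_cycles = 10, seed = 2)
  cyc <- segment_cycles(split_truth(s)$left, "left")
  expect_equal(nrow(cyc), 10)
  expect_true(all(cyc$contact_s < cyc$lift_s &
                    cyc$lift_s < cyc$next_contact_s))
  # stance + swing spans the cycle exactly
  expect_equal(cyc$stance_s + cyc$swing_s,
               cyc$next_contact_s - cyc$contact_s)
  # ends mid-swing: the incomplete cycle is excluded
  ev <- split_truth(s)$left
  ev_trunc <- ev[seq_len(nrow(ev) - 1), ]
  expect_equal(nrow(segment_cycles(ev_trunc)), 9)
  # shuffled events violate the ordering invariant
  ev_bad <- ev[c(2, 1, 3:nrow(ev)), ]
  expect_error(segment_cycles(ev_bad), "increasing|alternate")
})

test_that("step height implements max(swing) - mean(stance) and its invariances", {
  t <- seq(0, 1, by = 0.005)
  cyc <- list(contact_s = 0, lift_s = 0.6, next_contact_s = 1)
  y <- ifelse(t < 0.6, 1.0, 1.0 + 2.5 * sin(pi * (t - 0.6) / 0.4))
  expect_equal(step_height(cyc, t, y), 2.5, tolerance = 1e-3)
  # translation invariance
  expect_equal(step_height(cyc, t, y + 13.7),
               step_height(cyc, t, y), tolerance = 1e-12)
  # flat trajectory
  expect_equal(step_height(cyc, t, rep(2, length(t))), 0)
  expect_error(step_height(list(contact_s = 5, lift_s = 6,
                                next_contact_s = 7), t, y), "stance")
})

test_that("flexion velocity matches ramps and the half-sine closed form", {
  t <- seq(0, 1, by = 1 / 119.2)
  cyc <- list(contact_s = 0, lift_s = 0.5, next_contact_s = 1)
  ramp <- ifelse(t < 0.5, 0, 30 * (t - 0.5))
  expect_equal(flexion_velocity(cyc, t, ramp), 30, tolerance = 1e-9)
  expect_equal(flexion_velocity(cyc, t, rep(1, length(t))), 0)
  # half-sine arc of height h and duration T peaks at pi*h/T
  h <- 2; Tsw <- 0.4
  cyc2 <- list(contact_s = 0, lift_s = 0.5, next_contact_s = 0.5 + Tsw)
  arc <- ifelse(t >= 0.5 & t < 0.9, h * sin(pi * (t - 0.5) / Tsw), 0)
  expect_equal(flexion_velocity(cyc2, t, arc), pi * h / Tsw,
               tolerance = 0.05 * pi * h / Tsw)
  expect_error(flexion_velocity(list(contact_s = 0, lift_s = 0.99,
                                     next_contact_s = 0.995), t, ramp),
               "two frames")
})

test_that("asymmetry indices: literal formula, conventions, sign properties", {
  expect_equal(as.numeric(swing_asymmetry(0.10, 0.10)), 0)
  lit <- swing_asymmetry(0.129, 0.100, convention = "literal")
  expect_equal(as.numeric(lit), -0.29, tolerance = 1e-12)
  ip <- swing_asymmetry(0.129, 0.100)
  expect_equal(as.numeric(ip), 0.29, tolerance = 1e-12)
  expect_equal(attr(ip, "literal"), -0.29, tolerance = 1e-12)
  expect_equal(as.numeric(swing_asymmetry(0.08, 0.10, "literal")), 0.2)
  expect_equal(as.numeric(stance_asymmetry(0.2, 0.232, "literal")),
               1 - 0.2 / 0.232)
  # limb exchange flips the sign
  a <- as.numeric(stance_asymmetry(0.18, 0.24, "literal"))
  b <- as.numeric(stance_asymmetry(0.24, 0.18, "literal"))
  expect_lt(a * b, 0)
  expect_error(swing_asymmetry(0, 0.1), "positive")
})

test_that("posture height reports the mean and the baseline percentage", {
  t <- seq(0, 1, by = 0.01)
  cyc <- list(contact_s = 0, lift_s = 0.6, next_contact_s = 1)
  p <- posture_height(cyc, t, rep(5, length(t)), baseline = 5)
  expect_equal(p$percent, 100)
  expect_equal(posture_height(cyc, t, rep(4, length(t)), 5)$percent, 80)
  expect_error(posture_height(cyc, t, rep(4, length(t)), 0), "baseline")
})

test_that("dragging index spans its boundary cases", {
  t <- seq(0, 1, by = 0.01)
  cyc <- list(contact_s = 0, lift_s = 0.5, next_contact_s = 1)
  arc <- ifelse(t >= 0.5, 2 * sin(pi * (t - 0.5) / 0.5) + 1, 0)
  expect_equal(dragging_index(cyc, t, arc, ground_level = 0), 0)
  expect_equal(dragging_index(cyc, t, rep(0, length(t)), ground_level = 0), 1)
})

test_that("stimulus phase maps onsets to cycles and flags the coherence window", {
  ref <- c(1, 2, 3, 4)
  ph <- stimulus_phase(c(2, 2.5, 2.95, 10), ref)
  expect_equal(ph$phase[1], 0)
  expect_equal(ph$offset_s[1], 0)
  expect_equal(ph$phase[2], 0.5)
  expect_equal(ph$offset_s[3], -0.05, tolerance = 1e-12)
  expect_true(ph$phase_coherent[3])
  expect_false(ph$phase_coherent[2])
  expect_true(ph$excluded[4])
})
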