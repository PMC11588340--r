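#' Simulate a complete synthetic locomotor session
#'
#' Bundles the programmed event timeline, marker kinematics, EMG envelopes,
#' any delivered stimulation trains, and a `truth` record of every generator
#' parameter into a single session object. All randomness derives from the
#' single `seed`, fanned out deterministically per stage, so identical inputs
#' give bit-identical sessions.
#'
#' @param gait_params A [gait_model_params()] object.
#' @param injury An [injury_params()] object.
#' @param emg_params An [emg_model_params()] object.
#' @param n_cycles Number of complete gait cycles (>= 1).
#' @param seed Integer seed.
#' @param stims Optional stimulation event table (`onset_s`, `amplitude_uA`,
#'   `duration_ms`, `rate_hz`, `site_row`, `site_col`). If supplied together
#'   with `stim_model`, effects are applied via [apply_stimulation_effects()].
#' @param stim_model Optional [stim_effect_model()].
#' @return An object of class `cg_session` with elements `timeline`,
#'   `kinematics`, `emg`, `events_truth`, `stims`, and `truth`.
#' @export
simulate_session <- function(gait_params = gait_model_params(),
                             injury = injury_params("intact"),
                             emg_params = emg_model_params(),
                             n_cycles = 20, seed = 1L,
                             stims = NULL, stim_model = NULL) {
  timeline <- generate_gait_timeline(gait_params, injury, n_cycles,
                                     seed = child_seed(seed, 1))
  kin_seed <- child_seed(seed, 2)
  emg_seed <- child_seed(seed, 3)
  session <- structure(
    list(timeline = timeline,
         kinematics = generate_kinematics(timeline, seed = kin_seed),
         emg = generate_emg(timeline, emg_params, seed = emg_seed),
         events_truth = timeline$events,
         stims = empty_stim_table(),
         truth = list(gait_params = gait_params, injury = injury,
                      emg_params = emg_params, n_cycles = n_cycles,
                      seed = seed, kin_seed = kin_seed, emg_seed = emg_seed,
                      mods = check_cycle_mods(NULL, n_cycles),
                      stim_model = NULL)),
    class = "cg_session")
  if (!is.null(stims)) {
    stop_unless(!is.null(stim_model),
                "stims supplied without a stim_effect_model")
    session <- apply_stimulation_effects(session, stims, stim_model)
  }
  session
}

#' Apply phenomenological stimulation effects to a synthetic session
#'
#' For each delivered train the model computes the signed time offset from
#' train onset to the nearest contralateral (right) foot lift and evaluates
#' the phase kernel `K`: 1 within the +/-75 ms phase-coherence window and
#' raised-cosine decay to 0 over one further halfwidth. The gait cycle owning
#' that lift receives multiplicative effects `1 + gain * (A - amp_min) * K`
#' on contralateral step height, contralateral flexion velocity (via swing
#' arc peak advance), ipsilesional iliac crest height, and ipsilesional
#' extensor burst amplitude. Amplitudes at or below `amp_min` have no effect.
#' Kinematics and EMG are regenerated from the stored timeline and seeds, so
#' an empty stimulation table returns an identical session.
#'
#' @param session A `cg_session`.
#' @param stims Stimulation event table (see [simulate_session()]).
#' @param model A [stim_effect_model()].
#' @return A new `cg_session` with effects applied and `stims` attached.
#' @export
apply_stimulation_effects <- function(session, stims, model) {
  stopifnot(inherits(session, "cg_session"),
            inherits(model, "stim_effect_model"))
  stims <- as.data.frame(stims)
  need <- c("onset_s", "amplitude_uA")
  stop_unless(all(need %in% names(stims)),
              "stims must have onset_s and amplitude_uA columns")
  stop_unless(all(stims$amplitude_uA >= 0 &
                    stims$amplitude_uA <= model$amp_max),
              "stimulation amplitudes must lie in [0, amp_max]")

  tl <- session$timeline
  n <- tl$n_cycles
  mods <- check_cycle_mods(NULL, n)
  rl <- timeline_event_times(tl, "right", "lift")

  if (nrow(stims) > 0) {
    for (i in seq_len(nrow(stims))) {
      k <- which.min(abs(rl - stims$onset_s[i]))
      offset <- stims$onset_s[i] - rl[k]
      K <- phase_kernel(offset, model$phase_kernel_halfwidth)
      dA <- max(0, stims$amplitude_uA[i] - model$amp_min)
      if (K <= 0 || dA <= 0) next
      mods$step_mult_right[k] <- mods$step_mult_right[k] *
        (1 + model$gain_step_height * dA * K)
      mods$vel_mult_right[k] <- mods$vel_mult_right[k] *
        (1 + model$gain_flexion_velocity * dA * K)
      mods$crest_mult[k] <- mods$crest_mult[k] *
        (1 + model$gain_posture * dA * K)
      mods$img_mult[k] <- mods$img_mult[k] *
        (1 + model$gain_extensor_activation * dA * K)
    }
  }

  session$kinematics <- generate_kinematics(tl, seed = session$truth$kin_seed,
                                            mods = mods)
  session$emg <- generate_emg(tl, session$truth$emg_params,
                              seed = session$truth$emg_seed, mods = mods)
  session$stims <- normalize_stim_table(stims)
  session$truth$mods <- mods
  session$truth$stim_model <- model
  session
}

#' Phase kernel of the stimulation-effect model
#'
#' Equals 1 for offsets within one halfwidth of the reference event (the
#' phase-coherence window), decays to 0 as a raised cosine over one further
#' halfwidth, and is 0 beyond two halfwidths.
#'
#' @param offset_s Signed time offset from the reference gait event, s.
#' @param halfwidth Half-width of the coherence window, s.
#' @return Kernel values in `[0, 1]`.
#' @export
phase_kernel <- function(offset_s, halfwidth = 0.075) {
  stop_unless(halfwidth > 0, "halfwidth must be > 0")
  a <- abs(offset_s)
  ifelse(a <= halfwidth, 1,
         ifelse(a >= 2 * halfwidth, 0,
                0.5 * (1 + cos(pi * (a - halfwidth) / halfwidth))))
}

empty_stim_table <- function() {
  data.frame(onset_s = numeric(0), amplitude_uA = numeric(0),
             duration_ms = numeric(0), rate_hz = numeric(0),
             site_row = integer(0), site_col = integer(0))
}

normalize_stim_table <- function(stims) {
  out <- empty_stim_table()
  if (nrow(stims) == 0) return(out)
  stims$duration_ms <- stims$duration_ms %||% 40
  stims$rate_hz <- stims$rate_hz %||% 330
  stims$site_row <- stims$site_row %||% 1L
  stims$site_col <- stims$site_col %||% 1L
  stims[, names(out)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cg_session <- function(x, ...) {
  tl <- x$timeline
  cat(sprintf("<cg_session: %d cycles, %.1f s, injury '%s', %d stim trains>\n",
              tl$n_cycles, tl$t_end, tl$injury$severity, nrow(x$stims)))
  cat(sprintf("  kinematics: %d frames @ %.1f Hz; EMG: %d samples @ %g Hz\n",
              nrow(x$kinematics), tl$params$frame_rate, nrow(x$emg),
              x$truth$emg_params$sample_rate))
  invisible(x)
}
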