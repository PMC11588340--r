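#' Parameter objects for the synthetic locomotor session generator
#'
#' Constructors for the parameter bundles consumed by [simulate_session()] and
#' the lower-level generators. Each constructor validates its arguments and
#' returns a classed list so that downstream code can dispatch and re-validate.
#'
#' Defaults describe treadmill locomotion of an adult rat at 23 cm/s with
#' sagittal kinematics sampled at 119.2 Hz, the standard recording setup for
#' this preparation.
#'
#' @param cycle_duration Gait cycle duration in seconds.
#' @param duty_cycle_left,duty_cycle_right Fraction of the cycle spent in
#'   stance for each hindlimb (used when no timing asymmetry is imposed).
#' @param step_height_left,step_height_right Programmed swing arc height, cm.
#' @param crest_height Iliac crest height above the belt, cm.
#' @param belt_speed Treadmill belt speed, cm/s.
#' @param frame_rate Kinematic sampling rate, Hz.
#' @param noise_sd_kin Additive Gaussian noise SD on marker positions, cm.
#' @param cycle_jitter SD of the multiplicative per-cycle duration jitter
#'   (fraction of the cycle; all phases of a cycle are scaled jointly so
#'   within-cycle timing ratios are preserved).
#' @return An object of class `gait_model_params`.
#' @export
gait_model_params <- function(cycle_duration = 0.8,
                              duty_cycle_left = 0.65,
                              duty_cycle_right = 0.65,
                              step_height_left = 2.0,
                              step_height_right = 2.0,
                              crest_height = 5.0,
                              belt_speed = 23,
                              frame_rate = 119.2,
                              noise_sd_kin = 0.05,
                              cycle_jitter = 0.02) {
  stop_unless(cycle_duration > 0, "cycle_duration must be > 0")
  stop_unless(duty_cycle_left > 0 && duty_cycle_left < 1,
              "duty_cycle_left must lie in (0, 1)")
  stop_unless(duty_cycle_right > 0 && duty_cycle_right < 1,
              "duty_cycle_right must lie in (0, 1)")
  stop_unless(step_height_left >= 0 && step_height_right >= 0,
              "step heights must be non-negative")
  stop_unless(crest_height > 0, "crest_height must be > 0")
  stop_unless(belt_speed > 0, "belt_speed must be > 0")
  stop_unless(frame_rate > 0, "frame_rate must be > 0")
  stop_unless(noise_sd_kin >= 0, "noise_sd_kin must be non-negative")
  stop_unless(cycle_jitter >= 0 && cycle_jitter < 0.5,
              "cycle_jitter must lie in [0, 0.5)")
  structure(list(cycle_duration = cycle_duration,
                 duty_cycle_left = duty_cycle_left,
                 duty_cycle_right = duty_cycle_right,
                 step_height_left = step_height_left,
                 step_height_right = step_height_right,
                 crest_height = crest_height,
                 belt_speed = belt_speed,
                 frame_rate = frame_rate,
                 noise_sd_kin = noise_sd_kin,
                 cycle_jitter = cycle_jitter),
            class = "gait_model_params")
}

#' Injury (hemisection) deficit parameters
#'
#' Describes the locomotor deficits imposed on a synthetic session after a
#' left (ipsilesional) thoracic hemisection. Severity presets draw on the
#' deficits observed about one week after injury: ipsilateral swing dominance
#' of roughly 29%, contralateral stance dominance of roughly 16%, ankle
#' extensor burst duration reduced by 72% and total activation by 92%, a
#' lowered iliac crest and toe dragging.
#'
#' @param severity One of `"intact"`, `"mild"`, `"moderate"`, `"severe"`.
#'   Selects preset deficit magnitudes; explicit arguments override presets.
#' @param swing_dominance_ipsi Fractional excess of left (ipsilateral) swing
#'   duration over right: `SwLeft/SwRight - 1`.
#' @param stance_dominance_contra Fractional excess of right stance duration
#'   over left: `StRight/StLeft - 1`.
#' @param extensor_burst_duration_scale Ipsilateral MG burst duration as a
#'   fraction of intact.
#' @param extensor_activation_scale Ipsilateral MG total activation (burst
#'   integral) as a fraction of intact.
#' @param crest_drop Drop of the iliac crest height, cm.
#' @param drag_fraction Fraction of the swing phase the fourth toe spends at
#'   ground level (foot drop / dragging).
#' @param step_height_scale_ipsi Left swing arc height as a fraction of the
#'   programmed value (weak ipsilateral flexion).
#' @return An object of class `injury_params`.
#' @export
injury_params <- function(severity = c("moderate", "intact", "mild", "severe"),
                          swing_dominance_ipsi = NULL,
                          stance_dominance_contra = NULL,
                          extensor_burst_duration_scale = NULL,
                          extensor_activation_scale = NULL,
                          crest_drop = NULL,
                          drag_fraction = NULL,
                          step_height_scale_ipsi = NULL) {
  severity <- match.arg(severity)
  preset <- switch(severity,
    intact   = list(sw = 0,    st = 0,    bd = 1,    ba = 1,    cd = 0,   df = 0,   sh = 1),
    mild     = list(sw = 0.15, st = 0.08, bd = 0.60, ba = 0.40, cd = 0.5, df = 0.1, sh = 0.85),
    moderate = list(sw = 0.29, st = 0.16, bd = 0.28, ba = 0.08, cd = 1.0, df = 0.3, sh = 0.70),
    severe   = list(sw = 0.40, st = 0.24, bd = 0.15, ba = 0.04, cd = 1.5, df = 0.6, sh = 0.50))
  pick <- function(x, d) if (is.null(x)) d else x
  out <- list(severity = severity,
              swing_dominance_ipsi = pick(swing_dominance_ipsi, preset$sw),
              stance_dominance_contra = pick(stance_dominance_contra, preset$st),
              extensor_burst_duration_scale =
                pick(extensor_burst_duration_scale, preset$bd),
              extensor_activation_scale =
                pick(extensor_activation_scale, preset$ba),
              crest_drop = pick(crest_drop, preset$cd),
              drag_fraction = pick(drag_fraction, preset$df),
              step_height_scale_ipsi = pick(step_height_scale_ipsi, preset$sh))
  stop_unless(out$swing_dominance_ipsi >= 0, "swing_dominance_ipsi must be >= 0")
  stop_unless(out$stance_dominance_contra >= 0,
              "stance_dominance_contra must be >= 0")
  stop_unless(out$extensor_burst_duration_scale >= 0 &&
                out$extensor_burst_duration_scale <= 1,
              "extensor_burst_duration_scale must lie in [0, 1]")
  stop_unless(out$extensor_activation_scale >= 0 &&
                out$extensor_activation_scale <= 1,
              "extensor_activation_scale must lie in [0, 1]")
  stop_unless(out$crest_drop >= 0, "crest_drop must be non-negative")
  stop_unless(out$drag_fraction >= 0 && out$drag_fraction <= 1,
              "drag_fraction must lie in [0, 1]")
  stop_unless(out$step_height_scale_ipsi >= 0 && out$step_height_scale_ipsi <= 1,
              "step_height_scale_ipsi must lie in [0, 1]")
  # a timing asymmetry on one side only is not realisable with a common
  # cycle period; both dominances must be zero or both positive
  if (xor(out$swing_dominance_ipsi > 0, out$stance_dominance_contra > 0)) {
    stop("swing_dominance_ipsi and stance_dominance_contra must be both zero ",
         "or both positive: with a shared cycle period a swing excess on one ",
         "side forces a stance excess on the other", call. = FALSE)
  }
  structure(out, class = "injury_params")
}

#' Phenomenological stimulation-effect model
#'
#' Linear-in-amplitude, phase-gated model of the immediate kinematic and EMG
#' effects of short-train intracortical stimulation of the left motor cortex.
#' Effects are fractional increases per microampere above `amp_min`, gated by
#' a phase kernel centred on the contralateral (right) foot lift: the kernel
#' equals 1 within +/-`phase_kernel_halfwidth` of the lift (the phase-coherence
#' window) and decays to 0 as a raised cosine over one further halfwidth.
#'
#' @param amp_min,amp_max Functional stimulation range, uA. Amplitudes at or
#'   below `amp_min` have no effect.
#' @param gain_step_height Fractional increase of contralateral step height per
#'   uA above `amp_min`.
#' @param gain_flexion_velocity Additional fractional increase of contralateral
#'   flexion velocity per uA (applied by advancing the swing-arc peak; the
#'   velocity inherits the step-height gain on top of this).
#' @param gain_posture Fractional increase of iliac crest height per uA.
#' @param gain_extensor_activation Fractional increase of ipsilateral extensor
#'   (MG) burst amplitude per uA.
#' @param phase_kernel_center Reference gait event, currently only
#'   `"contralateral_lift"`.
#' @param phase_kernel_halfwidth Half-width of the phase-coherence window, s.
#' @return An object of class `stim_effect_model`.
#' @export
stim_effect_model <- function(amp_min = 30,
                              amp_max = 150,
                              gain_step_height = 0.01,
                              gain_flexion_velocity = 0,
                              gain_posture = 0.002,
                              gain_extensor_activation = 0.008,
                              phase_kernel_center = "contralateral_lift",
                              phase_kernel_halfwidth = 0.075) {
  stop_unless(amp_min < amp_max, "amp_min must be smaller than amp_max")
  stop_unless(amp_min >= 0, "amp_min must be non-negative")
  stop_unless(phase_kernel_halfwidth > 0, "phase_kernel_halfwidth must be > 0")
  gains <- c(gain_step_height, gain_flexion_velocity, gain_posture,
             gain_extensor_activation)
  stop_unless(all(is.finite(gains)), "gains must be finite")
  phase_kernel_center <- match.arg(phase_kernel_center, "contralateral_lift")
  structure(list(amp_min = amp_min, amp_max = amp_max,
                 gain_step_height = gain_step_height,
                 gain_flexion_velocity = gain_flexion_velocity,
                 gain_posture = gain_posture,
                 gain_extensor_activation = gain_extensor_activation,
                 phase_kernel_center = phase_kernel_center,
                 phase_kernel_halfwidth = phase_kernel_halfwidth),
            class = "stim_effect_model")
}

#' EMG envelope model parameters
#'
#' @param sample_rate EMG sampling rate, Hz (6 kHz, the standard recording
#'   rate for this preparation).
#' @param burst_amplitude Named vector of burst peak amplitudes, mV, for the
#'   muscles `iTA`, `cTA`, `iMG`, `cMG` (i = left/ipsilesional,
#'   c = right/contralesional; TA = tibialis anterior ankle flexor,
#'   MG = medial gastrocnemius ankle extensor).
#' @param burst_shape `"raised-cosine"` (default) or `"rect"`.
#' @param noise_sd_emg Additive Gaussian noise SD on the envelopes, mV
#'   (rectified to keep envelopes non-negative).
#' @return An object of class `emg_model_params`.
#' @export
emg_model_params <- function(sample_rate = 6000,
                             burst_amplitude = c(iTA = 0.5, cTA = 0.5,
                                                 iMG = 0.5, cMG = 0.5),
                             burst_shape = c("raised-cosine", "rect"),
                             noise_sd_emg = 0.01) {
  stop_unless(sample_rate > 0, "sample_rate must be > 0")
  stop_unless(all(burst_amplitude >= 0), "burst amplitudes must be >= 0")
  stop_unless(all(emg_muscles() %in% names(burst_amplitude)),
              "burst_amplitude must name all of iTA, cTA, iMG, cMG")
  stop_unless(noise_sd_emg >= 0, "noise_sd_emg must be non-negative")
  burst_shape <- match.arg(burst_shape)
  structure(list(sample_rate = sample_rate,
                 burst_amplitude = burst_amplitude[emg_muscles()],
                 burst_shape = burst_shape,
                 noise_sd_emg = noise_sd_emg),
            class = "emg_model_params")
}

#' Muscle identifiers used throughout the package
#' @return Character vector `c("iTA", "cTA", "iMG", "cMG")`.
#' @export
emg_muscles <- function() c("iTA", "cTA", "iMG", "cMG")

#' Marker identifiers used throughout the package
#'
#' Six sagittal markers per hindlimb: iliac crest, trochanter, knee, ankle,
#' fifth metatarsal (`mtp5`) and fourth toe tip (`toe4`). Analyses are driven
#' by `mtp5` (step height, flexion velocity, gait events), `toe4` (dragging)
#' and `crest` (posture); the remaining markers are generated by fixed
#' segment offsets for completeness.
#' @return Character vector of marker names.
#' @export
kinematic_markers <- function() {
  c("crest", "trochanter", "knee", "ankle", "mtp5", "toe4")
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @export
print.gait_model_params <- function(x, ...) {
  cat("<gait_model_params>\n")
  cat(sprintf("  cycle %.3g s, duty L/R %.2f/%.2f, belt %.3g cm/s, %g Hz\n",
              x$cycle_duration, x$duty_cycle_left, x$duty_cycle_right,
              x$belt_speed, x$frame_rate))
  cat(sprintf("  step height L/R %.2f/%.2f cm, crest %.2f cm, noise %.3g cm\n",
              x$step_height_left, x$step_height_right, x$crest_height,
              x$noise_sd_kin))
  invisible(x)
}

#' @export
print.injury_params <- function(x, ...) {
  cat(sprintf("<injury_params: %s>\n", x$severity))
  cat(sprintf("  swing dom (ipsi) %.2f, stance dom (contra) %.2f\n",
              x$swing_dominance_ipsi, x$stance_dominance_contra))
  cat(sprintf("  iMG duration x%.2f, activation x%.2f; crest drop %.2f cm; drag %.2f\n",
              x$extensor_burst_duration_scale, x$extensor_activation_scale,
              x$crest_drop, x$drag_fraction))
  invisible(x)
}
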