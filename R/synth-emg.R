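#' Generate synthetic EMG envelopes for a programmed timeline
#'
#' Produces envelope time series for the four recorded muscles: tibialis
#' anterior (ankle flexor) bursts span the swing phase of their limb, medial
#' gastrocnemius (ankle extensor) bursts span the stance phase. After a left
#' hemisection the ipsilesional extensor (iMG) is impaired: its burst
#' occupies only `extensor_burst_duration_scale` of the stance phase and its
#' amplitude is rescaled so that the burst integral (total activation) equals
#' `extensor_activation_scale` times the intact value.
#'
#' @param timeline A [generate_gait_timeline()] result.
#' @param emg_params An [emg_model_params()] object.
#' @param injury Override of the injury stored in `timeline`.
#' @param seed Integer seed for the additive envelope noise.
#' @param mods Optional per-cycle effect modifiers (see
#'   [apply_stimulation_effects()]); `img_mult` scales the ipsilesional
#'   extensor burst amplitude cycle by cycle.
#' @return A data.frame with `time_s` and one column per muscle (mV).
#'   Envelopes are non-negative everywhere.
#' @export
generate_emg <- function(timeline, emg_params = emg_model_params(),
                         injury = timeline$injury, seed = 1L, mods = NULL) {
  stopifnot(inherits(timeline, "gait_timeline"),
            inherits(emg_params, "emg_model_params"))
  n <- timeline$n_cycles
  mods <- check_cycle_mods(mods, n)

  t <- seq(0, timeline$t_end, by = 1 / emg_params$sample_rate)
  amp <- emg_params$burst_amplitude

  lc <- timeline_event_times(timeline, "left", "contact")
  ll <- timeline_event_times(timeline, "left", "lift")
  rc <- timeline_event_times(timeline, "right", "contact")
  rl <- timeline_event_times(timeline, "right", "lift")

  # burst windows per muscle: flexors in swing, extensors in stance
  win_iTA <- cbind(ll, lc[-1])
  win_cTA <- cbind(rl, rc[-1])
  win_cMG <- cbind(rc[seq_len(n)], rl)
  # impaired ipsilesional extensor: shortened burst at stance onset, with
  # amplitude rescaled so the integral scales by the activation fraction.
  # The duration scale is applied to the *intact* stance duration (duty cycle
  # times the jittered cycle period) so that burst duration and activation,
  # normalised against an intact baseline session, recover the programmed
  # scales exactly.
  dsc <- injury$extensor_burst_duration_scale
  asc <- injury$extensor_activation_scale
  st_intact <- timeline$params$duty_cycle_left * timeline$cycles$duration
  img_dur <- pmin(dsc * st_intact, ll - lc[seq_len(n)])
  win_iMG <- cbind(lc[seq_len(n)], lc[seq_len(n)] + img_dur)
  amp_iMG_scale <- if (dsc > 0) asc / dsc else 0

  env <- list(
    iTA = burst_train(t, win_iTA, amp[["iTA"]], emg_params$burst_shape),
    cTA = burst_train(t, win_cTA, amp[["cTA"]], emg_params$burst_shape),
    iMG = burst_train(t, win_iMG, amp[["iMG"]] * amp_iMG_scale * mods$img_mult,
                      emg_params$burst_shape),
    cMG = burst_train(t, win_cMG, amp[["cMG"]], emg_params$burst_shape)
  )

  out <- data.frame(time_s = t)
  with_seed(seed, {
    for (m in emg_muscles()) {
      out[[m]] <- pmax(0, env[[m]] +
                         stats::rnorm(length(t), 0, emg_params$noise_sd_emg))
    }
  })
  out
}

# sum of burst envelopes over [onset, offset) windows; amplitude may be a
# scalar or one value per window
burst_train <- function(t, windows, amplitude, shape) {
  y <- numeric(length(t))
  if (nrow(windows) == 0) return(y)
  amplitude <- rep_len(amplitude, nrow(windows))
  for (k in seq_len(nrow(windows))) {
    a <- windows[k, 1]; b <- windows[k, 2]
    if (b <= a || amplitude[k] <= 0) next
    idx <- t >= a & t < b
    if (shape == "rect") {
      y[idx] <- y[idx] + amplitude[k]
    } else {
      s <- (t[idx] - a) / (b - a)
      y[idx] <- y[idx] + amplitude[k] * 0.5 * (1 - cos(2 * pi * s))
    }
  }
  y
}
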