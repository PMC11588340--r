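#' Generate synthetic marker kinematics for a programmed timeline
#'
#' Samples sagittal marker trajectories at the configured frame rate. During
#' stance the foot sits at its resting height and travels backwards at belt
#' speed; during swing it follows a single-peaked half-sine vertical arc of
#' the programmed step height with linear forward progression. The iliac
#' crest sits at a constant height (minus the injury crest drop). Toe
#' dragging is modelled on the ipsilesional (left) fourth toe: for the first
#' `drag_fraction` of swing the toe stays at ground level.
#'
#' Non-foot markers (ankle, knee, trochanter) are placed by fixed segment
#' offsets from the foot and carry no independent information; analyses are
#' driven by the fifth metatarsal, fourth toe and iliac crest markers.
#'
#' @param timeline A [generate_gait_timeline()] result.
#' @param params,injury Override the parameter objects stored in `timeline`
#'   (rarely needed).
#' @param seed Integer seed for the additive Gaussian marker noise.
#' @param mods Optional per-cycle effect modifiers as produced by
#'   [apply_stimulation_effects()]; `NULL` means no stimulation effects.
#' @return A data.frame with `time_s` and one `<limb>_<marker>_<axis>_cm`
#'   column per limb, marker and axis (x forward, y vertical above belt).
#' @export
generate_kinematics <- function(timeline, params = timeline$params,
                                injury = timeline$injury, seed = 1L,
                                mods = NULL) {
  stopifnot(inherits(timeline, "gait_timeline"))
  stop_unless(params$frame_rate > 0, "frame_rate must be > 0")
  n <- timeline$n_cycles
  mods <- check_cycle_mods(mods, n)

  t <- seq(0, timeline$t_end, by = 1 / params$frame_rate)

  rest_mtp5 <- 0.3   # resting marker heights above belt, cm
  rest_toe4 <- 0.1

  h_left <- rep(params$step_height_left * injury$step_height_scale_ipsi, n)
  h_right <- params$step_height_right * mods$step_mult_right
  spk_left <- rep(0.5, n)
  spk_right <- pmin(pmax(0.5 / mods$vel_mult_right, 0.1), 0.9)

  lc <- timeline_event_times(timeline, "left", "contact")
  ll <- timeline_event_times(timeline, "left", "lift")
  rc <- timeline_event_times(timeline, "right", "contact")
  rl <- timeline_event_times(timeline, "right", "lift")

  l_mtp5 <- foot_path(t, lc, ll, h_left, spk_left, rest_mtp5,
                      params$belt_speed)
  r_mtp5 <- foot_path(t, rc, rl, h_right, spk_right, rest_mtp5,
                      params$belt_speed)
  l_toe4 <- foot_path(t, lc, ll, h_left, spk_left, rest_toe4,
                      params$belt_speed, drag_fraction = injury$drag_fraction,
                      lift_offset = 0.25)
  r_toe4 <- foot_path(t, rc, rl, h_right, spk_right, rest_toe4,
                      params$belt_speed, lift_offset = 0.25)

  # iliac crest: constant height with injury drop and per-cycle stimulation
  # modulation on the left (ipsilesional) side
  crest_base <- params$crest_height - injury$crest_drop
  l_crest_y <- rep(crest_base, length(t))
  cyc <- timeline$cycles
  for (k in seq_len(n)) {
    if (mods$crest_mult[k] != 1) {
      idx <- t >= cyc$t_start[k] & t < cyc$t_start[k] + cyc$duration[k]
      l_crest_y[idx] <- crest_base * mods$crest_mult[k]
    }
  }
  r_crest_y <- rep(params$crest_height, length(t))

  # fixed two-segment offsets for the cosmetic markers
  seg <- list(ankle = c(-0.8, 1.2), knee = c(-1.5, 3.2), trochanter = c(-0.8, 4.3))

  out <- data.frame(time_s = t)
  add <- function(nm, v) {
    out[[nm]] <<- v + stats::rnorm(length(v), 0, params$noise_sd_kin)
  }
  with_seed(seed, {
    for (limb in c("left", "right")) {
      mt <- if (limb == "left") l_mtp5 else r_mtp5
      to <- if (limb == "left") l_toe4 else r_toe4
      cr <- if (limb == "left") l_crest_y else r_crest_y
      add(paste0(limb, "_mtp5_x_cm"), mt$x)
      add(paste0(limb, "_mtp5_y_cm"), mt$y)
      add(paste0(limb, "_toe4_x_cm"), to$x + 1.2)
      add(paste0(limb, "_toe4_y_cm"), to$y)
      add(paste0(limb, "_crest_x_cm"), rep(-6, length(t)))
      add(paste0(limb, "_crest_y_cm"), cr)
      for (mk in names(seg)) {
        add(paste0(limb, "_", mk, "_x_cm"), mt$x + seg[[mk]][1])
        add(paste0(limb, "_", mk, "_y_cm"), mt$y * 0.3 + seg[[mk]][2])
      }
    }
  })
  out
}

# vertical swing arc: half-sine rising to h at swing fraction s_pk, half-sine
# descent after; max ascending velocity = h*pi/(2*s_pk*T_swing)
swing_arc <- function(s, h, s_pk) {
  ifelse(s <= s_pk,
         h * sin(pi / 2 * s / s_pk),
         h * cos(pi / 2 * (s - s_pk) / (1 - s_pk)))
}

# foot trajectory over the whole bout; contacts has one more element than
# lifts (the closing contact of the final cycle)
# lift_offset: height the marker snaps to the instant it leaves the ground
# (used for the toe, which clears the ground abruptly once released), so the
# fraction of swing spent within the dragging tolerance band reflects the
# programmed drag fraction rather than the arc's shallow take-off and landing
foot_path <- function(t, contacts, lifts, h, s_pk, rest, belt_speed,
                      drag_fraction = 0, lift_offset = 0) {
  n <- length(lifts)
  x <- numeric(length(t))
  y <- rep(rest, length(t))
  for (k in seq_len(n)) {
    st <- t >= contacts[k] & t < lifts[k]
    x[st] <- -belt_speed * (t[st] - contacts[k])
    sw <- t >= lifts[k] & t < contacts[k + 1]
    s <- (t[sw] - lifts[k]) / (contacts[k + 1] - lifts[k])
    x_lift <- -belt_speed * (lifts[k] - contacts[k])
    x[sw] <- x_lift * (1 - s)
    off <- if (h[k] > lift_offset) lift_offset else 0
    arc_k <- function(ss) off + swing_arc(ss, h[k] - off, s_pk[k])
    if (drag_fraction >= 1) {
      y[sw] <- rest
    } else if (drag_fraction > 0) {
      s2 <- pmax(0, (s - drag_fraction) / (1 - drag_fraction))
      y[sw] <- rest + ifelse(s < drag_fraction, 0, arc_k(s2))
    } else {
      y[sw] <- rest + arc_k(s)
    }
  }
  list(x = x, y = y)
}

# per-cycle multiplicative effect modifiers (identity when mods is NULL)
check_cycle_mods <- function(mods, n_cycles) {
  if (is.null(mods)) {
    return(data.frame(cycle = seq_len(n_cycles),
                      step_mult_right = 1, vel_mult_right = 1,
                      crest_mult = 1, img_mult = 1))
  }
  need <- c("cycle", "step_mult_right", "vel_mult_right", "crest_mult",
            "img_mult")
  stop_unless(all(need %in% names(mods)),
              "mods must have columns cycle, step_mult_right, vel_mult_right, crest_mult, img_mult")
  stop_unless(nrow(mods) == n_cycles, "mods must have one row per cycle")
  mods
}
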