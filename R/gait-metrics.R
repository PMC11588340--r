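#' Step height of one gait cycle
#'
#' Maximum vertical foot displacement during swing minus the average vertical
#' foot position during stance. Invariant to adding a constant to the whole
#' series.
#'
#' @param cycle One row of a [segment_cycles()] table (or any list with
#'   `contact_s`, `lift_s`, `next_contact_s`).
#' @param time_s,foot_y Sample times and vertical positions covering the cycle.
#' @return Step height, cm.
#' @export
step_height <- function(cycle, time_s, foot_y) {
  st <- time_s >= cycle$contact_s & time_s < cycle$lift_s
  sw <- time_s >= cycle$lift_s & time_s < cycle$next_contact_s
  stop_unless(any(st), "no samples in the stance window")
  stop_unless(any(sw), "no samples in the swing window")
  max(foot_y[sw]) - mean(foot_y[st])
}

#' Maximum vertical foot speed during the ascending part of swing
#'
#' Finite-difference vertical velocity, maximised from lift to the swing
#' apex (the hindlimb flexion portion of swing).
#'
#' @inheritParams step_height
#' @return Flexion velocity, cm/s.
#' @export
flexion_velocity <- function(cycle, time_s, foot_y) {
  sw <- which(time_s >= cycle$lift_s & time_s < cycle$next_contact_s)
  stop_unless(length(sw) >= 2, "swing must span at least two frames")
  y <- foot_y[sw]
  t <- time_s[sw]
  peak <- which.max(y)
  if (peak < 2) return(0)
  v <- diff(y[seq_len(peak)]) / diff(t[seq_len(peak)])
  max(v, 0)
}

#' Swing asymmetry index
#'
#' The literal definition is `1 - SwLeft/SwRight`: negative when the left
#' (ipsilateral) swing is longer. Under the `"ipsi-positive"` reporting
#' convention used in figures (positive values mean ipsilateral-side
#' dominance) the sign is flipped. The literal value is always retained as
#' the `"literal"` attribute.
#'
#' @param sw_left,sw_right Swing durations, s (both > 0).
#' @param convention `"ipsi-positive"` (default) or `"literal"`.
#' @return The asymmetry index, with attribute `literal`.
#' @export
swing_asymmetry <- function(sw_left, sw_right,
                            convention = c("ipsi-positive", "literal")) {
  asymmetry_index(sw_left, sw_right, match.arg(convention))
}

#' Stance asymmetry index
#'
#' `1 - StLeft/StRight` (literal), sign-flipped under the `"ipsi-positive"`
#' convention. See [swing_asymmetry()].
#'
#' @param st_left,st_right Stance durations, s (both > 0).
#' @inheritParams swing_asymmetry
#' @return The asymmetry index, with attribute `literal`.
#' @export
stance_asymmetry <- function(st_left, st_right,
                             convention = c("ipsi-positive", "literal")) {
  asymmetry_index(st_left, st_right, match.arg(convention))
}

asymmetry_index <- function(left, right, convention) {
  stop_unless(all(left > 0) && all(right > 0),
              "phase durations must be positive")
  literal <- 1 - left / right
  out <- if (convention == "literal") literal else -literal
  attr(out, "literal") <- literal
  out
}

#' Posture: iliac crest height over a gait cycle
#'
#' @param cycle One row of a [segment_cycles()] table.
#' @param time_s,crest_y Sample times and crest heights covering the cycle.
#' @param baseline Reference crest height (intact condition), cm.
#' @return A list with `mean_cm` and `percent` (100 x mean / baseline).
#' @export
posture_height <- function(cycle, time_s, crest_y, baseline) {
  stop_unless(is.numeric(baseline) && baseline > 0, "baseline must be > 0")
  idx <- time_s >= cycle$contact_s & time_s < cycle$next_contact_s
  stop_unless(any(idx), "no samples in the cycle window")
  m <- mean(crest_y[idx])
  list(mean_cm = m, percent = 100 * m / baseline)
}

#' Dragging index: fraction of swing spent at ground level
#'
#' Fraction of swing samples in which the toe stays within `tolerance` of
#' the ground (foot-drop dragging).
#'
#' @param cycle One row of a [segment_cycles()] table.
#' @param time_s,toe_y Sample times and toe heights covering the swing.
#' @param ground_level Ground reference height, cm; defaults to the mean toe
#'   height during the cycle's stance phase.
#' @param tolerance Height tolerance above ground, cm.
#' @return Fraction in `[0, 1]`.
#' @export
dragging_index <- function(cycle, time_s, toe_y, ground_level = NULL,
                           tolerance = 0.2) {
  sw <- time_s >= cycle$lift_s & time_s < cycle$next_contact_s
  if (!any(sw)) return(0)
  if (is.null(ground_level)) {
    st <- time_s >= cycle$contact_s & time_s < cycle$lift_s
    stop_unless(any(st), "no stance samples to estimate ground level")
    ground_level <- mean(toe_y[st])
  }
  mean(toe_y[sw] <= ground_level + tolerance)
}

#' Stimulus phase relative to a reference gait event
#'
#' Maps each train onset to the gait cycle that contains it, expressed as a
#' phase in `[0, 1)` from one reference event to the next, together with the
#' signed time offset to the nearest reference event. Onsets outside the
#' covered span are flagged and excluded from phase computation.
#'
#' @param onset_s Train onset times, s.
#' @param reference_times Sorted times of the reference gait event (by
#'   default the contralateral foot lifts; ipsilateral contacts are the
#'   common alternative).
#' @param coherence_halfwidth Half-width of the phase-coherence window, s.
#' @return A data.frame `onset_s`, `phase`, `offset_s`, `phase_coherent`,
#'   `excluded`.
#' @export
stimulus_phase <- function(onset_s, reference_times,
                           coherence_halfwidth = 0.075) {
  stop_unless(length(reference_times) >= 2,
              "need at least two reference events")
  reference_times <- sort(reference_times)
  k <- findInterval(onset_s, reference_times)
  excluded <- k < 1 | k >= length(reference_times)
  phase <- rep(NA_real_, length(onset_s))
  ok <- !excluded
  phase[ok] <- (onset_s[ok] - reference_times[k[ok]]) /
    (reference_times[k[ok] + 1] - reference_times[k[ok]])
  offset <- vapply(onset_s, function(o) {
    d <- o - reference_times
    d[which.min(abs(d))]
  }, numeric(1))
  data.frame(onset_s = onset_s, phase = phase, offset_s = offset,
             phase_coherent = abs(offset) <= coherence_halfwidth,
             excluded = excluded)
}

#' Per-cycle kinematic metrics for a session
#'
#' Runs the full kinematic pipeline: detects gait events from the configured
#' foot marker of each limb, segments cycles, and computes the standard
#' treadmill metrics per cycle.
#'
#' @param kinematics Kinematics data.frame from [generate_kinematics()] or a
#'   session bundle, or a `cg_session`.
#' @param foot_marker Marker used for events, step height and flexion
#'   velocity (default `"mtp5"`).
#' @param events Optional list with elements `left`/`right` of `gait_events`
#'   to use instead of running the detector (e.g. programmed truth events).
#' @param crest_baseline Baseline crest height for the posture percentage;
#'   `NA` skips the percentage.
#' @param drag_tolerance Tolerance for [dragging_index()], cm.
#' @param ... Passed to [detect_gait_events()].
#' @return A data.frame of class `cycle_metrics`: one row per limb and cycle
#'   with durations, step height, flexion velocity, posture and drag index.
#' @export
compute_cycle_metrics <- function(kinematics, foot_marker = "mtp5",
                                  events = NULL, crest_baseline = NA,
                                  drag_tolerance = 0.2, ...) {
  if (inherits(kinematics, "cg_session")) kinematics <- kinematics$kinematics
  t <- kinematics$time_s
  fs <- 1 / stats::median(diff(t))
  out <- list()
  for (limb in c("left", "right")) {
    foot_y <- kinematics[[paste0(limb, "_", foot_marker, "_y_cm")]]
    toe_y <- kinematics[[paste0(limb, "_toe4_y_cm")]]
    crest_y <- kinematics[[paste0(limb, "_crest_y_cm")]]
    stop_unless(!is.null(foot_y), paste0("missing marker column for ", limb))
    ev <- if (!is.null(events)) events[[limb]]
          else detect_gait_events(foot_y, fs, time_s = t, ...)
    cyc <- segment_cycles(ev, limb = limb)
    if (nrow(cyc) == 0) next
    cyc$step_height_cm <- NA_real_
    cyc$flexion_velocity_cm_s <- NA_real_
    cyc$posture_cm <- NA_real_
    cyc$posture_pct <- NA_real_
    cyc$drag_index <- NA_real_
    for (i in seq_len(nrow(cyc))) {
      ci <- cyc[i, ]
      cyc$step_height_cm[i] <- step_height(ci, t, foot_y)
      cyc$flexion_velocity_cm_s[i] <- flexion_velocity(ci, t, foot_y)
      if (!is.null(crest_y)) {
        cyc$posture_cm[i] <- mean(crest_y[t >= ci$contact_s &
                                            t < ci$next_contact_s])
        if (!is.na(crest_baseline)) {
          cyc$posture_pct[i] <- 100 * cyc$posture_cm[i] / crest_baseline
        }
      }
      if (!is.null(toe_y)) {
        cyc$drag_index[i] <- dragging_index(ci, t, toe_y,
                                            tolerance = drag_tolerance)
      }
    }
    out[[limb]] <- cyc
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cycle_metrics", "data.frame")
  res
}

#' Session-level asymmetry indices from a cycle-metrics table
#'
#' Mean swing and stance asymmetry over paired left/right cycles.
#'
#' @param metrics A [compute_cycle_metrics()] table.
#' @param convention Passed to [swing_asymmetry()].
#' @return A list with `swing` and `stance` indices.
#' @export
session_asymmetry <- function(metrics,
                              convention = c("ipsi-positive", "literal")) {
  convention <- match.arg(convention)
  l <- metrics[metrics$limb == "left", ]
  r <- metrics[metrics$limb == "right", ]
  n <- min(nrow(l), nrow(r))
  stop_unless(n >= 1, "need at least one cycle per limb")
  list(
    swing = as.numeric(swing_asymmetry(mean(l$swing_s[seq_len(n)]),
                                       mean(r$swing_s[seq_len(n)]),
                                       convention)),
    stance = as.numeric(stance_asymmetry(mean(l$stance_s[seq_len(n)]),
                                         mean(r$stance_s[seq_len(n)]),
                                         convention))
  )
}
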