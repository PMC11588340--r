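#' Detect foot contact and lift events from a marker trajectory
#'
#' Two-stage detector on the vertical trajectory of a foot marker (the fifth
#' metatarsal by default, which is least affected by toe drag). A coarse
#' swing mask — smoothed height above the estimated ground level plus a
#' robust threshold, debounced by a minimum phase duration — locates the
#' swing phases; each edge is then refined by interpolating the crossing of
#' a fine threshold just above ground, giving sub-frame event times.
#'
#' @param foot_y Vertical marker positions, cm.
#' @param frame_rate Sampling rate, Hz.
#' @param time_s Optional sample times; defaults to `(0:(n-1))/frame_rate`.
#' @param coarse_threshold Height above ground for the swing mask, cm.
#' @param fine_threshold Height above ground for edge refinement, cm.
#' @param min_phase Minimum credible phase duration, s (shorter runs are
#'   treated as noise and merged away).
#' @param smooth_frames Width of the centred moving-average smoother.
#' @return A data.frame of class `gait_events` with columns `time_s` and
#'   `event` (`"contact"`/`"lift"`), alternating, strictly increasing.
#'   Trajectories without a complete swing yield zero rows.
#' @export
detect_gait_events <- function(foot_y, frame_rate, time_s = NULL,
                               coarse_threshold = 0.12,
                               fine_threshold = 0.04,
                               min_phase = 0.05, smooth_frames = 3) {
  stop_unless(all(is.finite(foot_y)), "trajectory must be finite")
  stop_unless(frame_rate > 0, "frame_rate must be > 0")
  n <- length(foot_y)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / frame_rate
  if (n < 4) return(empty_gait_events())

  ys <- moving_average(foot_y, smooth_frames)
  ground <- stats::quantile(ys, 0.2, names = FALSE)
  mask <- ys > ground + coarse_threshold
  mask <- debounce_mask(mask, max(1L, round(min_phase * frame_rate)))
  d <- diff(c(FALSE, mask, FALSE))
  lifts_i <- which(d == 1)        # first swing sample
  contacts_i <- which(d == -1)    # first stance sample after swing
  # drop swing phases cut by the recording edges
  if (length(lifts_i) > 0 && lifts_i[1] == 1) {
    lifts_i <- lifts_i[-1]; contacts_i <- contacts_i[-1]
  }
  if (length(contacts_i) > 0 && contacts_i[length(contacts_i)] > n) {
    lifts_i <- lifts_i[-length(lifts_i)]
    contacts_i <- contacts_i[-length(contacts_i)]
  }
  if (length(lifts_i) == 0) return(empty_gait_events())

  lift_t <- vapply(lifts_i, refine_event, numeric(1),
                   y = ys, t = time_s, ground = ground,
                   fine = fine_threshold, direction = "up")
  contact_t <- vapply(contacts_i, refine_event, numeric(1),
                      y = ys, t = time_s, ground = ground,
                      fine = fine_threshold, direction = "down")

  ev <- rbind(data.frame(time_s = lift_t, event = "lift"),
              data.frame(time_s = contact_t, event = "contact"))
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

empty_gait_events <- function() {
  ev <- data.frame(time_s = numeric(0), event = character(0))
  class(ev) <- c("gait_events", "data.frame")
  ev
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

# remove mask runs shorter than min_run samples (alternately for both states)
debounce_mask <- function(mask, min_run) {
  r <- rle(mask)
  while (any(r$lengths < min_run) && length(r$lengths) > 1) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_run) break
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

# Sub-frame event refinement around the coarse edge at index i: the rising
# (or falling) flank of the swing arc between 0.1 and 0.5 cm above ground is
# fitted with a line and extrapolated to ground level, which is robust to
# marker noise (single-threshold crossings are biased early by noise runs).
# Falls back to direct interpolation of the fine-threshold crossing when the
# flank provides fewer than two usable samples.
refine_event <- function(i, y, t, ground, fine, direction) {
  n <- length(y)
  # contiguous flank adjacent to the edge only: walking into the swing arc
  # cannot pick up stance noise samples that happen to sit in the band
  band <- integer(0)
  if (direction == "up") {
    j <- i
    while (j <= min(n, i + 12) && y[j] <= ground + 0.5) {
      if (y[j] >= ground + 0.1) band <- c(band, j)
      j <- j + 1
    }
  } else {
    j <- i - 1
    while (j >= max(1, i - 13) && y[j] <= ground + 0.5) {
      if (y[j] >= ground + 0.1) band <- c(band, j)
      j <- j - 1
    }
  }
  if (length(band) >= 2 && stats::sd(t[band]) > 0) {
    b <- stats::cov(t[band], y[band]) / stats::var(t[band])
    ok <- if (direction == "up") b > 0 else b < 0
    if (ok && abs(b) > 1e-6) {
      a <- mean(y[band]) - b * mean(t[band])
      return((ground - a) / b)
    }
  }
  refine_crossing(i, y, t, ground + fine, direction)
}

# linear interpolation of the time where y crosses thr just before (up) or
# after (down) the coarse edge at index i
refine_crossing <- function(i, y, t, thr, direction) {
  n <- length(y)
  if (direction == "up") {
    j <- i
    while (j > 1 && y[j - 1] > thr) j <- j - 1
    if (j == 1) return(t[1])
    interp_cross(t[j - 1], t[j], y[j - 1], y[j], thr)
  } else {
    j <- i
    while (j <= n && y[j] > thr) j <- j + 1
    if (j > n) return(t[n])
    if (j == 1) return(t[1])
    interp_cross(t[j - 1], t[j], y[j - 1], y[j], thr)
  }
}

interp_cross <- function(t0, t1, y0, y1, thr) {
  if (y1 == y0) return(t1)
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Segment alternating gait events into cycles
#'
#' One cycle per (contact, lift, next contact) triple; partial cycles at the
#' ends are dropped. Events must alternate with strictly increasing times.
#'
#' @param events A `gait_events` data.frame (or any data.frame with `time_s`
#'   and `event` columns for one limb).
#' @param limb Optional limb label attached to the result.
#' @return A data.frame of class `gait_cycles`: `limb`, `cycle`,
#'   `contact_s`, `lift_s`, `next_contact_s`, `stance_s`, `swing_s`.
#' @export
segment_cycles <- function(events, limb = NA_character_) {
  stop_unless(is.data.frame(events) &&
                all(c("time_s", "event") %in% names(events)),
              "events must have time_s and event columns")
  if (nrow(events) > 1) {
    if (is.unsorted(events$time_s, strictly = TRUE)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    if (any(events$event[-1] == events$event[-nrow(events)])) {
      stop("events must alternate between contact and lift", call. = FALSE)
    }
  }
  ci <- which(events$event == "contact")
  cycles <- list()
  for (k in seq_along(ci)) {
    i <- ci[k]
    if (i + 2 > nrow(events)) break
    cycles[[length(cycles) + 1]] <- data.frame(
      limb = limb, cycle = length(cycles) + 1L,
      contact_s = events$time_s[i],
      lift_s = events$time_s[i + 1],
      next_contact_s = events$time_s[i + 2])
  }
  out <- if (length(cycles) == 0) {
    data.frame(limb = character(0), cycle = integer(0), contact_s = numeric(0),
               lift_s = numeric(0), next_contact_s = numeric(0))
  } else do.call(rbind, cycles)
  out$stance_s <- out$lift_s - out$contact_s
  out$swing_s <- out$next_contact_s - out$lift_s
  class(out) <- c("gait_cycles", "data.frame")
  out
}
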