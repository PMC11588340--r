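#' Count alternating hindlimb rhythm repetitions after a long train
#'
#' Classifies the post-train response from the burst times of the two ankle
#' flexors. No bursts at all gives `"none"`; bursts on one side only give
#' `"unilateral"`; temporally overlapping left/right bursts give
#' `"bilateral_non_alternated"` (flagged); otherwise bursts are paired
#' greedily in time order, one left with one right burst (order-agnostic
#' start), and each complete pair counts as one repetition — `n_repetitions
#' >= 1` exactly when the classification is `"bilateral_alternated"`.
#'
#' @param left_bursts,right_bursts [detect_bursts()] tables (or data.frames
#'   with `onset_s`/`offset_s`) from the two tibialis anterior envelopes.
#' @param window Post-train window `c(from, to)`, s; bursts whose onset
#'   falls outside are ignored. Default uses all supplied bursts.
#' @return An object of class `rhythm_result`: list with `classification`,
#'   `n_repetitions`, `flagged`, and `bursts` (time-ordered, with side).
#' @export
count_alternations <- function(left_bursts, right_bursts, window = NULL) {
  pick <- function(b, side) {
    if (is.null(b) || nrow(b) == 0) {
      return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                        side = character(0)))
    }
    out <- data.frame(onset_s = b$onset_s, offset_s = b$offset_s, side = side)
    if (!is.null(window)) {
      out <- out[out$onset_s >= window[1] & out$onset_s <= window[2], ]
    }
    out
  }
  b <- rbind(pick(left_bursts, "L"), pick(right_bursts, "R"))
  b <- b[order(b$onset_s), ]
  rownames(b) <- NULL

  res <- function(cls, nrep, flagged = FALSE) {
    structure(list(classification = cls, n_repetitions = as.integer(nrep),
                   flagged = flagged, bursts = b), class = "rhythm_result")
  }
  if (nrow(b) == 0) return(res("none", 0))
  if (all(b$side == "L") || all(b$side == "R")) return(res("unilateral", 0))

  overlap <- FALSE
  if (nrow(b) > 1) {
    overlap <- any(b$onset_s[-1] < b$offset_s[-nrow(b)] &
                     b$side[-1] != b$side[-nrow(b)])
  }
  if (overlap) return(res("bilateral_non_alternated", 0, flagged = TRUE))

  # greedy pairing: a repetition is one burst followed by one on the other
  # side (L-R or R-L, depending on which side starts)
  nrep <- 0L
  i <- 1L
  while (i < nrow(b)) {
    if (b$side[i] != b$side[i + 1]) {
      nrep <- nrep + 1L
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (nrep >= 1) res("bilateral_alternated", nrep) else
    res("bilateral_non_alternated", 0, flagged = TRUE)
}

#' Classify an evoked rhythm directly from two envelopes
#'
#' Convenience wrapper: [detect_bursts()] on both tibialis anterior
#' envelopes within the post-train window, then [count_alternations()]. A
#' burst must clear the pre-train baseline by 4 noise SDs, so quiescent
#' (e.g. sedated) recordings classify as `"none"` rather than promoting
#' noise to bursts.
#'
#' @param emg Data.frame with `time_s`, `iTA`, `cTA` (e.g. from
#'   [generate_rhythm_response()]).
#' @param train_onset_s Train onset, s.
#' @param window_s Length of the post-train analysis window, s (default 2).
#' @param ... Passed to [detect_bursts()].
#' @return A `rhythm_result` (see [count_alternations()]).
#' @export
classify_rhythm <- function(emg, train_onset_s = 0, window_s = 2, ...) {
  floor_for <- function(x) {
    pre <- x[emg$time_s < train_onset_s]
    if (length(pre) < 10) return(0)
    # clear both the 4-SD criterion and anything seen at rest, so long
    # noise excursions are never promoted to bursts
    max(mean(pre) + 4 * stats::sd(pre), 1.5 * max(pre))
  }
  lb <- detect_bursts(emg$iTA, time_s = emg$time_s,
                      min_peak = floor_for(emg$iTA), ...)
  rb <- detect_bursts(emg$cTA, time_s = emg$time_s,
                      min_peak = floor_for(emg$cTA), ...)
  count_alternations(lb, rb, window = c(train_onset_s,
                                        train_onset_s + window_s))
}

#' @export
print.rhythm_result <- function(x, ...) {
  cat(sprintf("<rhythm_result: %s, %d repetition(s)%s>\n",
              x$classification, x$n_repetitions,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' Ladder (horizontal rungs) paw-placement score
#'
#' Percentage of steps with a partial or correct paw placement on the
#' rungs; session scores average five trials.
#'
#' @param n_correct,n_partial,n_total Step counts for one hindlimb; vectors
#'   are treated as repeated trials and averaged.
#' @return Placement percentage in `[0, 100]` (mean over trials).
#' @export
ladder_score <- function(n_correct, n_partial, n_total) {
  stop_unless(all(n_total > 0), "n_total must be positive")
  stop_unless(all(n_correct >= 0) && all(n_partial >= 0),
              "counts must be non-negative")
  stop_unless(all(n_correct + n_partial <= n_total),
              "placements cannot exceed total steps")
  mean(100 * (n_correct + n_partial) / n_total)
}

#' Classify injury severity from week-1 ladder performance
#'
#' Severity classes follow the skilled-locomotion criteria: severe when the
#' right hindlimb scores below 75% (bilateral deficit); otherwise mild when
#' the left hindlimb scores above 20%, else moderate. The printed rules use
#' strict inequalities, so exact-boundary values are assigned to the less
#' severe adjacent class and flagged.
#'
#' @param left_pct,right_pct Paw-placement percentages for the left and
#'   right hindlimb.
#' @return A list with `severity` (`"mild"`, `"moderate"`, `"severe"`) and
#'   `boundary` (`TRUE` when a value sat exactly on a class boundary).
#' @export
classify_severity <- function(left_pct, right_pct) {
  stop_unless(left_pct >= 0 && left_pct <= 100 &&
                right_pct >= 0 && right_pct <= 100,
              "percentages must lie in [0, 100]")
  boundary <- right_pct == 75 || left_pct == 20
  severity <- if (right_pct < 75) "severe"
              else if (left_pct > 20) "mild"
              else if (left_pct < 20) "moderate"
              else "mild"  # left exactly 20: less severe adjacent class
  list(severity = severity, boundary = boundary)
}

#' Open-field locomotor rubric (20-point scale)
#'
#' Constructor for the eight-item open-field locomotor rubric used to score
#' spontaneous locomotion after thoracic injury: (i) articular movement
#' amplitude of hip, knee and ankle (0-2 each); (ii) stationary and active
#' weight support (0-1 each); (iii) digit position (0-2); (iv) paw placement
#' at contact (0-2); (v) paw orientation at lift (1-2); (vi) swing movement
#' (1-2); (vii) fore-hindlimb coordination (0-3); (viii) tail position
#' (0-1). Maximum total: 20.
#'
#' @param joint_hip,joint_knee,joint_ankle 0 absent, 1 slight, 2 normal.
#' @param weight_stationary,weight_active 0 absent, 1 present.
#' @param digit_position 0 flexed, 1 atonic, 2 extended.
#' @param paw_placement 0 dorsal, 1 rotated, 2 parallel.
#' @param paw_orientation 1 rotated, 2 parallel.
#' @param swing_movement 1 irregular, 2 regular.
#' @param coordination 0 absent, 1 occasional, 2 frequent, 3 consistent.
#' @param tail 0 down, 1 up.
#' @return An object of class `openfield_rubric`.
#' @export
openfield_rubric <- function(joint_hip = 2, joint_knee = 2, joint_ankle = 2,
                             weight_stationary = 1, weight_active = 1,
                             digit_position = 2, paw_placement = 2,
                             paw_orientation = 2, swing_movement = 2,
                             coordination = 3, tail = 1) {
  vals <- list(joint_hip = joint_hip, joint_knee = joint_knee,
               joint_ankle = joint_ankle,
               weight_stationary = weight_stationary,
               weight_active = weight_active,
               digit_position = digit_position,
               paw_placement = paw_placement,
               paw_orientation = paw_orientation,
               swing_movement = swing_movement,
               coordination = coordination, tail = tail)
  rng <- openfield_ranges()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!(is.numeric(v) && length(v) == 1 && v == round(v) &&
            v >= rng[[nm]][1] && v <= rng[[nm]][2])) {
      stop(sprintf("sub-score '%s' must be an integer in [%d, %d]",
                   nm, rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
    }
  }
  structure(vals, class = "openfield_rubric")
}

openfield_ranges <- function() {
  list(joint_hip = c(0, 2), joint_knee = c(0, 2), joint_ankle = c(0, 2),
       weight_stationary = c(0, 1), weight_active = c(0, 1),
       digit_position = c(0, 2), paw_placement = c(0, 2),
       paw_orientation = c(1, 2), swing_movement = c(1, 2),
       coordination = c(0, 3), tail = c(0, 1))
}

#' Total open-field locomotor score
#'
#' Sum of the rubric sub-scores (0 to the 20-point maximum; the attainable
#' minimum is 2 because paw orientation and swing movement start at 1).
#'
#' @param rubric An [openfield_rubric()].
#' @return Integer total score.
#' @export
openfield_score <- function(rubric) {
  stopifnot(inherits(rubric, "openfield_rubric"))
  sum(unlist(rubric))
}
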