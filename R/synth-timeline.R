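#' Generate the programmed gait event timeline
#'
#' Builds per-limb foot contact and lift times for a bout of treadmill
#' locomotion. Both hindlimbs share a common cycle period; the right limb is
#' offset by half a cycle. Injury timing deficits are imposed through the
#' swing/stance dominance parameters: with a shared period the four phase
#' durations are uniquely determined by the cycle duration and the two
#' dominance ratios, so the programmed events reproduce the requested
#' asymmetry indices exactly (up to per-cycle jitter, which scales all phases
#' of a cycle jointly and therefore preserves the ratios).
#'
#' @param params A [gait_model_params()] object.
#' @param injury An [injury_params()] object.
#' @param n_cycles Number of complete gait cycles for each limb (>= 1).
#' @param seed Integer seed; identical inputs give bit-identical timelines.
#' @return An object of class `gait_timeline`: a list with
#'   \describe{
#'     \item{events}{data.frame `time_s`, `limb` (`"left"`/`"right"`),
#'       `event` (`"contact"`/`"lift"`), `cycle`.}
#'     \item{cycles}{data.frame of per-cycle phase durations
#'       (`cycle, t_start, duration, stance_left, swing_left, stance_right,
#'       swing_right`).}
#'     \item{t_end}{end of the simulated bout, s.}
#'   }
#' @export
generate_gait_timeline <- function(params, injury, n_cycles, seed = 1L) {
  stopifnot(inherits(params, "gait_model_params"),
            inherits(injury, "injury_params"))
  stop_unless(is.numeric(n_cycles) && n_cycles >= 1,
              "n_cycles must be a positive count")
  n_cycles <- as.integer(n_cycles)

  split <- phase_split(params, injury)

  with_seed(seed, {
    # jitter scales whole cycles; truncate to keep durations positive
    m <- 1 + stats::rnorm(n_cycles + 1L, 0, params$cycle_jitter)
    m <- pmax(m, 0.5)
    durs <- params$cycle_duration * m
    t_start <- c(0, cumsum(durs))[seq_len(n_cycles + 1L)]

    cyc <- data.frame(
      cycle = seq_len(n_cycles + 1L),
      t_start = t_start,
      duration = durs,
      stance_left = split$stance_left * m,
      swing_left = split$swing_left * m,
      stance_right = split$stance_right * m,
      swing_right = split$swing_right * m
    )

    # left limb: contact at cycle start; right limb offset by half a cycle
    ev <- rbind(
      data.frame(time_s = cyc$t_start, limb = "left", event = "contact",
                 cycle = cyc$cycle),
      data.frame(time_s = cyc$t_start + cyc$stance_left, limb = "left",
                 event = "lift", cycle = cyc$cycle),
      data.frame(time_s = cyc$t_start + 0.5 * cyc$duration, limb = "right",
                 event = "contact", cycle = cyc$cycle),
      data.frame(time_s = cyc$t_start + 0.5 * cyc$duration + cyc$stance_right,
                 limb = "right", event = "lift", cycle = cyc$cycle)
    )
    # keep n_cycles complete cycles per limb: the (n+1)-th cycle contributes
    # only the closing contacts
    keep <- !(ev$cycle == n_cycles + 1L & ev$event == "lift")
    ev <- ev[keep, ]
    ev <- ev[order(ev$limb, ev$time_s), ]
    rownames(ev) <- NULL

    structure(list(events = ev,
                   cycles = cyc[seq_len(n_cycles), ],
                   n_cycles = n_cycles,
                   t_end = max(ev$time_s) + 0.25 * params$cycle_duration,
                   params = params, injury = injury, seed = seed),
              class = "gait_timeline")
  })
}

# Solve the stance/swing split. With a shared cycle period T and dominance
# ratios SwL = (1+dsw)*SwR, StR = (1+dst)*StL, the four durations are pinned:
#   SwR = dst*T / ((1+dst)(1+dsw) - 1)
# For an intact animal (both dominances zero) the duty-cycle parameters apply.
phase_split <- function(params, injury) {
  T <- params$cycle_duration
  dsw <- injury$swing_dominance_ipsi
  dst <- injury$stance_dominance_contra
  if (dsw == 0 && dst == 0) {
    st_l <- params$duty_cycle_left * T
    st_r <- params$duty_cycle_right * T
    return(list(stance_left = st_l, swing_left = T - st_l,
                stance_right = st_r, swing_right = T - st_r))
  }
  denom <- (1 + dst) * (1 + dsw) - 1
  sw_r <- dst * T / denom
  sw_l <- (1 + dsw) * sw_r
  st_l <- T - sw_l
  st_r <- T - sw_r
  if (any(c(sw_r, sw_l, st_l, st_r) <= 0) ||
      any(c(sw_r, sw_l, st_l, st_r) >= T)) {
    stop("requested dominance values give non-positive phase durations",
         call. = FALSE)
  }
  list(stance_left = st_l, swing_left = sw_l,
       stance_right = st_r, swing_right = sw_r)
}

#' @export
print.gait_timeline <- function(x, ...) {
  cat(sprintf("<gait_timeline: %d cycles, %.2f s, injury '%s'>\n",
              x$n_cycles, x$t_end, x$injury$severity))
  invisible(x)
}

# per-limb event times of a given type, in order
timeline_event_times <- function(timeline, limb, event) {
  ev <- timeline$events
  ev$time_s[ev$limb == limb & ev$event == event]
}
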