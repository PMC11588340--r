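#' Biphasic stimulation train template
#'
#' Short trains (40 ms) are used for phase-coherent gait modulation, long
#' trains (250 ms) for evoking locomotor-like rhythms; both at 330 Hz with
#' charge-balanced biphasic pulses of 200 us per phase, cathodic first.
#'
#' @param onset Train onset time, s (0 for a template).
#' @param duration Train duration, s.
#' @param rate Pulse rate, Hz.
#' @param pulse_width Per-phase pulse width, s.
#' @param polarity Currently only `"cathodic-first"`.
#' @param amplitude Current amplitude, uA.
#' @param site Array site `c(row, col)`.
#' @return An object of class `stim_train`. `pulse_onsets(train)` gives the
#'   individual pulse times.
#' @export
stim_train <- function(onset = 0, duration = 0.040, rate = 330,
                       pulse_width = 200e-6, polarity = "cathodic-first",
                       amplitude = 100, site = c(1L, 1L)) {
  stop_unless(duration > 0, "duration must be > 0")
  stop_unless(rate > 0, "rate must be > 0")
  stop_unless(pulse_width > 0, "pulse_width must be > 0")
  stop_unless(amplitude >= 0, "amplitude must be >= 0")
  polarity <- match.arg(polarity, "cathodic-first")
  structure(list(onset = onset, duration = duration, rate = rate,
                 pulse_width = pulse_width, polarity = polarity,
                 amplitude = amplitude, site = as.integer(site)),
            class = "stim_train")
}

#' Pulse onset times of a train
#'
#' `n_pulses = floor(duration * rate)`, evenly spaced at `1/rate` from the
#' train onset; flooring guarantees every pulse lies within
#' `[onset, onset + duration]`.
#'
#' @param train A [stim_train()].
#' @return Numeric vector of pulse onset times, s.
#' @export
pulse_onsets <- function(train) {
  stopifnot(inherits(train, "stim_train"))
  n <- floor(train$duration * train$rate)
  train$onset + (seq_len(n) - 1) / train$rate
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train: onset %.3f s, %g ms @ %g Hz, %g uA, %d pulses>\n",
              x$onset, x$duration * 1000, x$rate, x$amplitude,
              floor(x$duration * x$rate)))
  invisible(x)
}

#' Closed-loop trigger configuration
#'
#' @param source_muscle Muscle whose envelope drives the trigger.
#' @param threshold Activation threshold, mV. The threshold is always chosen
#'   explicitly (per session, as in the experimental protocol);
#'   [suggest_threshold()] offers a data-driven starting point but is never
#'   applied silently.
#' @param delay Delay from trigger to train onset, s.
#' @param refractory Minimum interval between triggers, s. Must exceed the
#'   train duration; default 0.25 s gives one trigger per gait cycle.
#' @param train A [stim_train()] template.
#' @return An object of class `trigger_config`.
#' @export
trigger_config <- function(source_muscle = "iTA", threshold, delay = 0.160,
                           refractory = 0.250, train = stim_train()) {
  stop_unless(is.numeric(threshold) && threshold > 0,
              "threshold must be a positive value in mV")
  stop_unless(delay >= 0, "delay must be >= 0")
  stopifnot(inherits(train, "stim_train"))
  stop_unless(refractory > train$duration,
              "refractory must exceed the train duration")
  structure(list(source_muscle = source_muscle, threshold = threshold,
                 delay = delay, refractory = refractory, train = train),
            class = "trigger_config")
}

#' Causal online EMG envelope (moving RMS)
#'
#' Root-mean-square over a trailing window: the value at time `t` uses only
#' samples at or before `t` (partial windows at the start average over the
#' available samples), so the envelope is causal by construction and
#' non-negative everywhere.
#'
#' @param signal Uniformly sampled signal (raw or already an envelope).
#' @param sample_rate Sampling rate, Hz.
#' @param window Window length, s (default 20 ms).
#' @return Numeric envelope of the same length as `signal`.
#' @export
compute_envelope <- function(signal, sample_rate, window = 0.020) {
  stop_unless(length(signal) > 0, "signal must be non-empty")
  stop_unless(sample_rate > 0, "sample_rate must be > 0")
  stop_unless(window > 0, "window must be > 0")
  n <- max(1L, round(window * sample_rate))
  cs <- cumsum(signal^2)
  lag <- if (length(signal) <= n) rep(0, length(signal))
         else c(rep(0, n), cs[seq_len(length(signal) - n)])
  width <- pmin(seq_along(signal), n)
  sqrt(pmax(0, (cs - lag) / width))
}

#' Detect threshold-crossing trigger events
#'
#' A trigger fires at the first sample where the envelope rises from below
#' to at or above the threshold; subsequent crossings within the refractory
#' period are suppressed.
#'
#' @param envelope Causal envelope samples.
#' @param config A [trigger_config()].
#' @param sample_rate Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param state Optional carried state from a previous chunk (see
#'   [run_closed_loop()]).
#' @return Numeric vector of trigger times (empty when no crossings).
#' @export
detect_triggers <- function(envelope, config, sample_rate, t0 = 0,
                            state = NULL) {
  detect_triggers_state(envelope, config, sample_rate, t0, state)$triggers
}

# trigger detection with explicit carried state: `prev` is the last envelope
# sample of the previous chunk, `last_trigger` the most recent trigger time
detect_triggers_state <- function(envelope, config, sample_rate, t0 = 0,
                                  state = NULL) {
  stopifnot(inherits(config, "trigger_config"))
  prev <- if (is.null(state)) -Inf else state$prev
  last_trigger <- if (is.null(state)) -Inf else state$last_trigger
  th <- config$threshold
  above <- envelope >= th
  prev_above <- c(prev >= th, above[-length(above)])
  rising <- which(above & !prev_above)
  times <- t0 + (rising - 1) / sample_rate
  keep <- logical(length(times))
  for (i in seq_along(times)) {
    if (times[i] - last_trigger >= config$refractory) {
      keep[i] <- TRUE
      last_trigger <- times[i]
    }
  }
  list(triggers = times[keep],
       state = list(prev = envelope[length(envelope)],
                    last_trigger = last_trigger))
}

#' Schedule a stimulation train from a trigger
#'
#' @param trigger Trigger time, s.
#' @param config A [trigger_config()].
#' @return A [stim_train()] with onset `trigger + delay`, inheriting the
#'   template's duration, rate, amplitude and site.
#' @export
schedule_train <- function(trigger, config) {
  stopifnot(inherits(config, "trigger_config"))
  tr <- config$train
  tr$onset <- trigger + config$delay
  tr
}

#' Run the closed-loop controller over a session stream
#'
#' Emulates the real-time pipeline: causal envelope of the source muscle,
#' threshold trigger with refractory, fixed delay, train scheduling. The
#' result is identical to applying [compute_envelope()], [detect_triggers()]
#' and [schedule_train()] offline; a decision at time `t` never uses samples
#' after `t`. Supplying `state` allows the stream to be processed in chunks
#' with bit-identical output.
#'
#' @param emg EMG data.frame (`time_s` plus one column per muscle) or a
#'   `cg_session`.
#' @param config A [trigger_config()].
#' @param envelope_window Online envelope window, s.
#' @param state Carried controller state from a previous chunk, or `NULL`.
#' @param raw If `FALSE` (default) the input is already an envelope and the
#'   online RMS stage is skipped in favour of direct thresholding.
#' @return A list with `log` (data.frame `trigger_s`, `onset_s`,
#'   `amplitude_uA`, `duration_ms`, `rate_hz`, `site_row`, `site_col`) and
#'   `state` (for stream continuation).
#' @export
run_closed_loop <- function(emg, config, envelope_window = 0.020,
                            state = NULL, raw = FALSE) {
  if (inherits(emg, "cg_session")) emg <- emg$emg
  stop_unless(is.data.frame(emg) && "time_s" %in% names(emg),
              "emg must be a data.frame with a time_s column")
  stop_unless(config$source_muscle %in% names(emg),
              paste0("source muscle '", config$source_muscle,
                     "' not found in the EMG table"))
  t <- emg$time_s
  stop_unless(nrow(emg) > 1, "need at least two samples")
  if (is.unsorted(t, strictly = TRUE)) {
    stop("out-of-order samples in the stream", call. = FALSE)
  }
  fs <- 1 / stats::median(diff(t))
  sig <- emg[[config$source_muscle]]
  env <- if (raw) compute_envelope(sig, fs, envelope_window) else sig
  # carried envelope state: the RMS window is re-primed from the carried
  # buffer so chunked processing matches a single pass
  if (raw && !is.null(state) && length(state$buffer) > 0) {
    n <- max(1L, round(envelope_window * fs))
    joined <- c(state$buffer, sig)
    env_full <- compute_envelope(joined, fs, envelope_window)
    env <- env_full[(length(state$buffer) + 1):length(joined)]
  }
  det <- detect_triggers_state(env, config, fs, t0 = t[1],
                               state = state$trigger)
  trains <- lapply(det$triggers, schedule_train, config = config)
  log <- if (length(trains) == 0) {
    cbind(data.frame(trigger_s = numeric(0)), empty_stim_table())
  } else {
    data.frame(trigger_s = det$triggers,
               onset_s = vapply(trains, `[[`, numeric(1), "onset"),
               amplitude_uA = config$train$amplitude,
               duration_ms = config$train$duration * 1000,
               rate_hz = config$train$rate,
               site_row = config$train$site[1],
               site_col = config$train$site[2])
  }
  n_keep <- if (raw) max(1L, round(envelope_window * fs)) - 1L else 0L
  new_state <- list(trigger = det$state,
                    buffer = if (n_keep > 0)
                      utils::tail(sig, n_keep) else numeric(0))
  list(log = log, state = new_state)
}

#' Suggest a trigger threshold from baseline activity
#'
#' Returns `3 * SD` of the envelope over a quiet baseline segment plus its
#' mean. Offered as a starting point only; the threshold in
#' [trigger_config()] must always be set explicitly.
#'
#' @param envelope Envelope samples from a baseline (quiet) segment.
#' @return Suggested threshold, mV.
#' @export
suggest_threshold <- function(envelope) {
  stop_unless(length(envelope) > 1, "need baseline samples")
  mean(envelope) + 3 * stats::sd(envelope)
}

#' Linearly spaced amplitude sweep over the functional range
#'
#' @param amp_min,amp_max Functional range bounds, uA.
#' @param n Number of levels (default 4: off plus low/medium/high, i.e. 33%,
#'   66% and 100% of the functional range).
#' @return Numeric vector of amplitudes from `amp_min` to `amp_max`.
#' @export
amplitude_sweep <- function(amp_min, amp_max, n = 4) {
  stop_unless(amp_min < amp_max, "amp_min must be below amp_max")
  stop_unless(n >= 2, "need at least two levels")
  seq(amp_min, amp_max, length.out = n)
}

#' Delay sweep covering the gait cycle
#'
#' Flexor-triggered protocols sweep 0-200 ms, extensor-triggered protocols
#' 80-280 ms, both in 40 ms steps.
#'
#' @param source `"flexor"` or `"extensor"`.
#' @param step Step size, s.
#' @return Numeric vector of delays, s.
#' @export
delay_sweep <- function(source = c("flexor", "extensor"), step = 0.040) {
  source <- match.arg(source)
  if (source == "flexor") seq(0, 0.200, by = step)
  else seq(0.080, 0.280, by = step)
}

#' Tune the trigger delay to hit the contralateral foot lift
#'
#' Given trigger times and the session's programmed (or detected) right-limb
#' lift events, returns the median interval from trigger to the next right
#' lift — the delay that centres train delivery on the phase-coherence
#' window.
#'
#' @param triggers Trigger times, s.
#' @param right_lifts Right (contralateral) foot lift times, s.
#' @return Delay in seconds.
#' @export
tune_delay <- function(triggers, right_lifts) {
  stop_unless(length(triggers) > 0, "no triggers supplied")
  gaps <- vapply(triggers, function(tr) {
    nxt <- right_lifts[right_lifts >= tr]
    if (length(nxt) == 0) NA_real_ else nxt[1] - tr
  }, numeric(1))
  stats::median(gaps, na.rm = TRUE)
}
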