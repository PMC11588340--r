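#' Detect EMG bursts in an envelope
#'
#' Maximal intervals where the envelope stays at or above
#' `threshold_fraction` times a reference level (by default the 95th
#' percentile of the envelope over the recording), after fusing gaps shorter
#' than `merge_gap` and discarding intervals shorter than `min_duration`.
#'
#' @param envelope Non-negative envelope samples, mV.
#' @param time_s Sample times; defaults to `(0:(n-1))/sample_rate`.
#' @param sample_rate Sampling rate, Hz (ignored when `time_s` is given).
#' @param threshold_fraction Fraction of the reference level (default 0.2).
#' @param min_duration Minimum burst duration, s (default 30 ms).
#' @param merge_gap Sub-threshold gaps shorter than this are fused, s.
#' @param reference Absolute reference level, mV; default
#'   `quantile(envelope, 0.95)`.
#' @param min_peak Absolute peak floor, mV: bursts whose peak stays below
#'   this value are discarded (guards against pure-noise envelopes, whose
#'   relative threshold would otherwise scale down to the noise floor).
#' @return A data.frame of class `emg_bursts`: `onset_s`, `offset_s`,
#'   `duration_s`, `peak_mV`, `area_mVs` — disjoint and ordered. An all-zero
#'   envelope yields zero rows.
#' @export
detect_bursts <- function(envelope, time_s = NULL, sample_rate = NULL,
                          threshold_fraction = 0.2, min_duration = 0.030,
                          merge_gap = 0.010, reference = NULL,
                          min_peak = 0) {
  stop_unless(all(envelope >= 0), "envelope must be non-negative")
  n <- length(envelope)
  if (is.null(time_s)) {
    stop_unless(!is.null(sample_rate), "supply time_s or sample_rate")
    time_s <- (seq_len(n) - 1) / sample_rate
  }
  dt <- stats::median(diff(time_s))
  if (is.null(reference)) {
    reference <- stats::quantile(envelope, 0.95, names = FALSE)
  }
  thr <- threshold_fraction * reference
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), peak_mV = numeric(0),
                      area_mVs = numeric(0))
  class(empty) <- c("emg_bursts", "data.frame")
  if (thr <= 0 || all(envelope < thr)) return(empty)

  mask <- envelope >= thr
  mask <- debounce_mask(!mask, max(1L, round(merge_gap / dt))) |> (\(m) !m)()
  d <- diff(c(FALSE, mask, FALSE))
  on_i <- which(d == 1)
  off_i <- which(d == -1)  # first sample after the burst
  keep <- (time_s[pmin(off_i, n)] - time_s[on_i]) >= min_duration
  on_i <- on_i[keep]; off_i <- off_i[keep]
  if (length(on_i) == 0) return(empty)
  out <- data.frame(
    onset_s = time_s[on_i],
    offset_s = time_s[pmin(off_i, n)] + ifelse(off_i > n, dt, 0),
    peak_mV = vapply(seq_along(on_i), function(k)
      max(envelope[on_i[k]:(min(off_i[k], n) - 0)]), numeric(1)),
    area_mVs = vapply(seq_along(on_i), function(k)
      trapz_integral(time_s[on_i[k]:min(off_i[k] - 1, n)],
                     envelope[on_i[k]:min(off_i[k] - 1, n)]), numeric(1))
  )
  out$duration_s <- out$offset_s - out$onset_s
  out <- out[, c("onset_s", "offset_s", "duration_s", "peak_mV", "area_mVs")]
  out <- out[out$peak_mV >= min_peak, ]
  rownames(out) <- NULL
  class(out) <- c("emg_bursts", "data.frame")
  out
}

trapz_integral <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Total activation: time integral of the envelope over a window
#'
#' Trapezoidal integral of the envelope between `from` and `to` (typically a
#' burst interval). Additive over disjoint windows.
#'
#' @param envelope Envelope samples, mV.
#' @param time_s Sample times, s.
#' @param from,to Window bounds, s.
#' @return Total activation, mV s.
#' @export
total_activation <- function(envelope, time_s, from, to) {
  stop_unless(to > from, "window must have positive length")
  idx <- time_s >= from & time_s <= to
  stop_unless(sum(idx) >= 2, "window contains fewer than two samples")
  trapz_integral(time_s[idx], envelope[idx])
}

#' Normalize metric values to a baseline condition
#'
#' @param values Metric values (e.g. burst durations under stimulation).
#' @param baseline Metric values from the baseline condition (pre-injury
#'   spontaneous locomotion of the same muscle).
#' @return A list with `fraction` (`values / mean(baseline)`), `percent`
#'   (100 x fraction) and `percent_change` (100 x (fraction - 1)).
#' @export
normalize_to_baseline <- function(values, baseline) {
  m <- mean(baseline)
  stop_unless(is.finite(m) && m > 0, "baseline mean must be positive")
  fraction <- values / m
  list(fraction = fraction, percent = 100 * fraction,
       percent_change = 100 * (fraction - 1))
}

#' Cycle-normalized average EMG envelope
#'
#' Resamples the envelope of every complete gait cycle onto `n_bins` equally
#' spaced phase bins and averages pointwise, the standard display of muscle
#' activity over the normalized gait cycle. The mean positions of the gait
#' events (limb lift, i.e. the stance/swing transition) are reported in bins.
#'
#' @param envelope Envelope samples, mV.
#' @param time_s Sample times, s.
#' @param cycles A [segment_cycles()] table for the reference limb.
#' @param n_bins Number of phase bins (default 100).
#' @return A list with `phase` (bin centres in `[0,1)`), `mean`, `sem`,
#'   `n_cycles` and `lift_phase` (mean stance-to-swing transition phase).
#' @export
cycle_normalized_envelope <- function(envelope, time_s, cycles,
                                      n_bins = 100) {
  stop_unless(nrow(cycles) >= 1, "need at least one complete cycle")
  phase <- (seq_len(n_bins) - 0.5) / n_bins
  mat <- matrix(NA_real_, nrow(cycles), n_bins)
  for (i in seq_len(nrow(cycles))) {
    tt <- cycles$contact_s[i] +
      phase * (cycles$next_contact_s[i] - cycles$contact_s[i])
    mat[i, ] <- stats::approx(time_s, envelope, xout = tt, rule = 2)$y
  }
  list(phase = phase,
       mean = colMeans(mat),
       sem = apply(mat, 2, stats::sd) / sqrt(nrow(cycles)),
       n_cycles = nrow(cycles),
       lift_phase = mean(cycles$stance_s /
                           (cycles$next_contact_s - cycles$contact_s)))
}

#' Per-cycle EMG metrics for a session
#'
#' Detects the principal burst of each muscle within every gait cycle of its
#' reference limb and reports burst duration and total activation (the
#' integral over the detected burst).
#'
#' @param emg EMG data.frame (`time_s` + muscle columns) or `cg_session`.
#' @param cycles_left,cycles_right [segment_cycles()] tables for the two
#'   limbs (flexors are referenced to their limb's swing, extensors to its
#'   stance).
#' @param muscles Muscles to quantify.
#' @param ... Passed to [detect_bursts()].
#' @return A data.frame: `muscle`, `cycle`, `burst_duration_s`,
#'   `total_activation_mVs` (NA when no burst was found in the cycle).
#' @export
compute_emg_metrics <- function(emg, cycles_left, cycles_right,
                                muscles = emg_muscles(), ...) {
  if (inherits(emg, "cg_session")) emg <- emg$emg
  res <- list()
  for (m in muscles) {
    stop_unless(m %in% names(emg), paste0("muscle '", m, "' not in EMG table"))
    cyc <- if (substr(m, 1, 1) == "i") cycles_left else cycles_right
    bursts <- detect_bursts(emg[[m]], time_s = emg$time_s, ...)
    for (i in seq_len(nrow(cyc))) {
      # the burst whose midpoint falls inside the cycle
      mid <- (bursts$onset_s + bursts$offset_s) / 2
      hit <- which(mid >= cyc$contact_s[i] & mid < cyc$next_contact_s[i])
      res[[length(res) + 1]] <- data.frame(
        muscle = m, cycle = cyc$cycle[i],
        burst_duration_s = if (length(hit)) max(bursts$duration_s[hit])
                           else NA_real_,
        total_activation_mVs = if (length(hit)) sum(bursts$area_mVs[hit])
                               else NA_real_)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
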