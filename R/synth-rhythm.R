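#' Generate bilateral flexor envelopes evoked by a long stimulation train
#'
#' Emulates the hindlimb responses to long-train (250 ms, 330 Hz) cortical
#' stimulation in a resting animal. In the intact condition and after mild
#' injury the train recruits a bilateral alternating flexor rhythm (1 to 3
#' complete left-right repetitions); one week after a severe hemisection
#' only contralateral bursts are evoked; under ketamine sedation no rhythmic
#' bursts appear.
#'
#' @param condition One of `"intact"`, `"sci_mild_wk1"`, `"sci_severe_wk1"`,
#'   `"ketamine"`.
#' @param train A [stim_train()]; defaults to a 250 ms, 330 Hz, 100 uA train
#'   starting at 0.5 s.
#' @param seed Integer seed.
#' @param n_repetitions Number of complete alternating repetitions to
#'   programme for rhythmic conditions; default draws 1-3.
#' @param sample_rate Envelope sampling rate, Hz.
#' @param window_s Length of the recording after train onset, s.
#' @param noise_sd Envelope noise SD, mV.
#' @return A list with `emg` (data.frame `time_s`, `iTA`, `cTA`),
#'   `train`, `condition`, and `truth` (programmed burst times per side).
#' @export
generate_rhythm_response <- function(condition = c("intact", "sci_mild_wk1",
                                                   "sci_severe_wk1",
                                                   "ketamine"),
                                     train = NULL, seed = 1L,
                                     n_repetitions = NULL,
                                     sample_rate = 6000, window_s = 2,
                                     noise_sd = 0.005) {
  condition <- match.arg(condition)
  if (is.null(train)) {
    train <- stim_train(onset = 0.5, duration = 0.250, rate = 330,
                        amplitude = 100)
  }
  stopifnot(inherits(train, "stim_train"))

  with_seed(seed, {
    if (is.null(n_repetitions)) n_repetitions <- sample(1:3, 1)
    stop_unless(n_repetitions >= 1, "n_repetitions must be >= 1")

    t <- seq(0, train$onset + window_s, by = 1 / sample_rate)
    period <- 0.4           # evoked rhythm period, s
    burst_w <- 0.15         # burst width, s
    lat <- 0.06             # response latency after train onset, s
    t0 <- train$onset + lat

    left_on <- right_on <- numeric(0)
    if (condition %in% c("intact", "sci_mild_wk1")) {
      # alternating L-R pairs: contralateral (right) limb leads the evoked
      # rhythm, the ipsilateral limb follows half a period later
      right_on <- t0 + (seq_len(n_repetitions) - 1) * period
      left_on <- right_on + period / 2
    } else if (condition == "sci_severe_wk1") {
      right_on <- t0 + (seq_len(n_repetitions) - 1) * period
    }
    # ketamine: no rhythmic bursts at all

    iTA <- burst_train(t, cbind(left_on, left_on + burst_w), 0.4,
                       "raised-cosine")
    cTA <- burst_train(t, cbind(right_on, right_on + burst_w), 0.4,
                       "raised-cosine")
    emg <- data.frame(
      time_s = t,
      iTA = pmax(0, iTA + stats::rnorm(length(t), 0, noise_sd)),
      cTA = pmax(0, cTA + stats::rnorm(length(t), 0, noise_sd))
    )
    list(emg = emg, train = train, condition = condition,
         truth = list(n_repetitions = if (condition == "ketamine") 0L
                      else as.integer(n_repetitions),
                      left_onsets = left_on, right_onsets = right_on,
                      burst_width = burst_w, period = period))
  })
}
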