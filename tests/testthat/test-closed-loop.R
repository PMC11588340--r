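test_that("the causal envelope matches a brute-force moving RMS", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  sig <- abs(sin(2 * pi * 8 * t))
  win <- 0.020
  env <- compute_envelope(sig, fs, win)
  n <- round(win * fs)
  brute <- vapply(seq_along(sig), function(i) {
    w <- sig[max(1, i - n + 1):i]
    sqrt(mean(w^2))
  }, numeric(1))
  expect_lt(max(abs(env - brute)), 1e-9)
})

test_that("envelope edge cases: zero input, steady state, empty signal", {
  expect_equal(compute_envelope(rep(0, 100), 1000), rep(0, 100))
  env <- compute_envelope(rep(2, 100), 1000, window = 0.02)
  expect_equal(env[21:100], rep(2, 80))
  expect_error(compute_envelope(numeric(0), 1000), "non-empty")
})

test_that("triggers fire on rising crossings and honour the refractory", {
  fs <- 1000
  cfg <- trigger_config("iTA", threshold = 0.5, refractory = 0.250)
  # always below threshold: silence
  expect_length(detect_triggers(rep(0.2, 500), cfg, fs), 0)
  # one constructed crossing at sample 101 (0-based time 0.100 s)
  env <- c(rep(0.1, 100), rep(0.9, 100))
  tr <- detect_triggers(env, cfg, fs)
  expect_equal(tr, 0.100)
  # two crossings 50 ms apart with a 250 ms refractory: only the first fires
  env2 <- c(rep(0.1, 100), rep(0.9, 20), rep(0.1, 30), rep(0.9, 20),
            rep(0.1, 100))
  expect_equal(detect_triggers(env2, cfg, fs), 0.100)
  # spaced beyond the refractory: both fire
  env3 <- c(rep(0.1, 100), rep(0.9, 20), rep(0.1, 300), rep(0.9, 20))
  expect_length(detect_triggers(env3, cfg, fs), 2)
})

test_that("train scheduling adds the delay and floors the pulse count", {
  cfg <- trigger_config("iTA", threshold = 0.1, delay = 0.160)
  tr <- schedule_train(1.000, cfg)
  expect_equal(tr$onset, 1.160)
  short <- stim_train(duration = 0.040, rate = 330)
  expect_length(pulse_onsets(short), 13)       # floor(0.040 * 330)
  long <- stim_train(duration = 0.250, rate = 330)
  expect_length(pulse_onsets(long), 82)        # floor(0.250 * 330)
  # every pulse lies within [onset, onset + duration]
  p <- pulse_onsets(schedule_train(2, trigger_config("iTA", 0.1,
                                                     train = long,
                                                     refractory = 0.3)))
  expect_true(all(p >= 2 + 0.160 - 1e-12 &
                    p <= 2 + 0.160 + long$duration + 1e-12))
})

test_that("chunked streaming reproduces the single-pass log exactly", {
  s <- moderate_session(seed = 21)
  cfg <- trigger_config("iTA", threshold = 0.2, delay = 0.1,
                        train = stim_train(amplitude = 80))
  for (raw in c(FALSE, TRUE)) {
    one <- run_closed_loop(s$emg, cfg, raw = raw)
    for (cut in c(100, 2557, 9000)) {
      a <- run_closed_loop(s$emg[seq_len(cut), ], cfg, raw = raw)
      b <- run_closed_loop(s$emg[-seq_len(cut), ], cfg, raw = raw,
                           state = a$state)
      expect_equal(rbind(a$log, b$log), one$log, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("online run equals the offline envelope-trigger-schedule chain", {
  s <- moderate_session(seed = 22)
  cfg <- trigger_config("iTA", threshold = 0.2, delay = 0.12)
  fs <- 1 / median(diff(s$emg$time_s))
  env <- compute_envelope(s$emg$iTA, fs, 0.020)
  trig <- detect_triggers(env, cfg, fs, t0 = s$emg$time_s[1])
  onsets <- vapply(trig, function(tt) schedule_train(tt, cfg)$onset,
                   numeric(1))
  on <- run_closed_loop(s$emg, cfg, raw = TRUE)
  expect_equal(on$log$trigger_s, trig, tolerance = 1e-12)
  expect_equal(on$log$onset_s, onsets, tolerance = 1e-12)
})

test_that("the controller is causal: truncation never changes earlier output", {
  s <- moderate_session(seed = 23)
  cfg <- trigger_config("iTA", threshold = 0.2, delay = 0.1)
  full <- run_closed_loop(s$emg, cfg)$log
  t_cut <- 6.0
  part <- run_closed_loop(s$emg[s$emg$time_s <= t_cut, ], cfg)$log
  keep <- full[full$trigger_s <= t_cut, ]
  expect_equal(part, keep, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("inter-trigger intervals never violate the refractory period", {
  s <- moderate_session(seed = 24)
  cfg <- trigger_config("iTA", threshold = 0.15, refractory = 0.250)
  log <- run_closed_loop(s$emg, cfg)$log
  expect_gt(nrow(log), 3)
  expect_true(all(diff(log$trigger_s) >= 0.250 - 1e-12))
})

test_that("a threshold above the envelope maximum yields an empty log", {
  s <- moderate_session(seed = 25)
  cfg <- trigger_config("iTA", threshold = 50)
  expect_equal(nrow(run_closed_loop(s$emg, cfg)$log), 0)
})

test_that("out-of-order streams are rejected", {
  s <- moderate_session(seed = 26)
  emg <- s$emg
  emg$time_s[10] <- emg$time_s[12]
  cfg <- trigger_config("iTA", threshold = 0.2)
  expect_error(run_closed_loop(emg, cfg), "out-of-order")
})

test_that("tuned flexor-triggered delays put >=90% of trains in the coherence window", {
  hits <- numeric(0)
  for (seed in c(31, 32)) {
    s <- moderate_session(seed = seed)
    probe <- run_closed_loop(s, trigger_config("iTA", 0.2, delay = 0))
    rl <- s$timeline$events$time_s[s$timeline$events$limb == "right" &
                                     s$timeline$events$event == "lift"]
    d <- tune_delay(probe$log$trigger_s, rl)
    log <- run_closed_loop(s, trigger_config("iTA", 0.2, delay = d))$log
    ph <- stimulus_phase(log$onset_s, rl)
    hits <- c(hits, ph$phase_coherent[!ph$excluded])
  }
  expect_gte(mean(hits), 0.9)
})

test_that("sweep helpers span the protocol ranges", {
  expect_equal(amplitude_sweep(30, 150, 4), c(30, 70, 110, 150))
  expect_equal(delay_sweep("flexor"), seq(0, 0.2, by = 0.04))
  expect_equal(delay_sweep("extensor"), seq(0.08, 0.28, by = 0.04))
  expect_gt(suggest_threshold(abs(rnorm(500, 0, 0.01))), 0)
})
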