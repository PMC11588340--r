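#' Default end-to-end pipeline configuration
#'
#' Bundles every tunable of the demonstration pipeline: session size, injury
#' severity, stimulation-effect model, closed-loop trigger settings and the
#' amplitude sweep. All fields can be overridden via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `cg_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_cycles = 20,
    injury = "moderate",
    gait_params = gait_model_params(),
    emg_params = emg_model_params(),
    stim_model = stim_effect_model(),
    amp_levels = 4,
    source_muscle = "iTA",
    threshold_mV = 0.2,
    refractory_s = 0.25,
    stimulation = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  stop_unless(length(unknown) == 0,
              paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "cg_config")
}

#' Run the full simulate-stimulate-analyse pipeline
#'
#' Executes the complete closed-loop experiment on synthetic data:
#' \enumerate{
#'   \item simulate an intact baseline session and an injured spontaneous
#'     session;
#'   \item for each amplitude of the sweep, run the closed-loop controller
#'     on a fresh injured session (trigger on the ipsilateral flexor, delay
#'     tuned to the contralateral foot lift) and apply the stimulation
#'     effects;
#'   \item compute per-cycle kinematic and EMG metrics for every session;
#'   \item fit dose-response lines (with VAF) of contralateral step height,
#'     flexion velocity, posture and ipsilateral extensor activation against
#'     amplitude, build the phase-binned effect profile, and run the
#'     no-stimulation versus maximum-stimulation comparison.
#' }
#' Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, the report tables are
#'   written as CSV files.
#' @return A list of class `cg_report`: `config`, `cycles` (all sessions),
#'   `emg_metrics`, `fits`, `phase_profile`, `tests`, `asymmetry`,
#'   `stim_log`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cg_config"))
  seed <- config$seed
  model <- config$stim_model

  intact <- simulate_session(config$gait_params, injury_params("intact"),
                             config$emg_params, config$n_cycles,
                             seed = child_seed(seed, 11))
  injured <- simulate_session(config$gait_params, injury_params(config$injury),
                              config$emg_params, config$n_cycles,
                              seed = child_seed(seed, 12))

  amps <- if (config$stimulation)
    amplitude_sweep(model$amp_min, model$amp_max, config$amp_levels)
  else numeric(0)

  sessions <- list(intact = intact, spontaneous = injured)
  stim_logs <- list()
  for (i in seq_along(amps)) {
    s <- simulate_session(config$gait_params, injury_params(config$injury),
                          config$emg_params, config$n_cycles,
                          seed = child_seed(seed, 20 + i))
    cl <- closed_loop_stims(s, config, amplitude = amps[i])
    s <- apply_stimulation_effects(s, cl$log, model)
    sessions[[paste0("amp_", round(amps[i]))]] <- s
    stim_logs[[i]] <- cbind(cl$log, amplitude_level = i)
  }

  crest_baseline <- config$gait_params$crest_height
  cycles <- do.call(rbind, lapply(names(sessions), function(nm) {
    cm <- compute_cycle_metrics(sessions[[nm]],
                                crest_baseline = crest_baseline)
    cbind(session = nm, cm)
  }))

  emg_metrics <- do.call(rbind, lapply(names(sessions), function(nm) {
    s <- sessions[[nm]]
    ev <- split_events(s$events_truth)
    cl <- segment_cycles(ev$left, "left")
    cr <- segment_cycles(ev$right, "right")
    cbind(session = nm, compute_emg_metrics(s, cl, cr))
  }))

  fits <- pipeline_fits(cycles, emg_metrics, amps, names(sessions))
  profile <- pipeline_phase_profile(sessions, amps)
  tests <- pipeline_tests(cycles, names(sessions), amps)
  asym <- do.call(rbind, lapply(names(sessions), function(nm) {
    a <- session_asymmetry(cycles[cycles$session == nm, ])
    data.frame(session = nm, swing = a$swing, stance = a$stance)
  }))

  report <- structure(
    list(config = config, cycles = cycles, emg_metrics = emg_metrics,
         fits = fits, phase_profile = profile, tests = tests,
         asymmetry = asym,
         stim_log = if (length(stim_logs)) do.call(rbind, stim_logs)
                    else empty_stim_table(),
         provenance = list(seed = seed,
                           package_version =
                             as.character(utils::packageVersion("corticogait")),
                           r_version = R.version.string,
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "cg_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# split a truth/detected event table into per-limb gait_events
split_events <- function(events) {
  out <- lapply(c(left = "left", right = "right"), function(l) {
    ev <- events[events$limb == l, c("time_s", "event")]
    ev <- ev[order(ev$time_s), ]
    rownames(ev) <- NULL
    class(ev) <- c("gait_events", "data.frame")
    ev
  })
  out
}

# deliver closed-loop stimulation on a session at one amplitude
closed_loop_stims <- function(session, config, amplitude) {
  model <- config$stim_model
  train <- stim_train(duration = 0.040, rate = 330, amplitude = amplitude)
  cfg0 <- trigger_config(config$source_muscle, config$threshold_mV,
                         delay = 0, refractory = config$refractory_s,
                         train = train)
  probe <- run_closed_loop(session, cfg0)
  rl <- timeline_event_times(session$timeline, "right", "lift")
  stop_unless(nrow(probe$log) > 0, "closed loop produced no triggers")
  delay <- tune_delay(probe$log$trigger_s, rl)
  cfg <- trigger_config(config$source_muscle, config$threshold_mV,
                        delay = delay, refractory = config$refractory_s,
                        train = train)
  run_closed_loop(session, cfg)
}

# per-metric dose-response fits over the amplitude sweep (session means of
# stimulated cycles; the no-stimulation session is not part of the fit, the
# sweep starts at the zero-effect amplitude amp_min)
pipeline_fits <- function(cycles, emg_metrics, amps, session_names) {
  if (length(amps) < 3) return(NULL)
  stim_names <- paste0("amp_", round(amps))
  mean_metric <- function(nm, col, limb) {
    d <- cycles[cycles$session == nm & cycles$limb == limb, ]
    mean(d[[col]], na.rm = TRUE)
  }
  mean_act <- function(nm) {
    d <- emg_metrics[emg_metrics$session == nm & emg_metrics$muscle == "iMG", ]
    mean(d$total_activation_mVs, na.rm = TRUE)
  }
  metrics <- list(
    step_height = vapply(stim_names, mean_metric, numeric(1),
                         col = "step_height_cm", limb = "right"),
    flexion_velocity = vapply(stim_names, mean_metric, numeric(1),
                              col = "flexion_velocity_cm_s", limb = "right"),
    posture = vapply(stim_names, mean_metric, numeric(1),
                     col = "posture_cm", limb = "left"),
    extensor_activation = vapply(stim_names, mean_act, numeric(1))
  )
  do.call(rbind, lapply(names(metrics), function(m) {
    fit <- linear_fit_vaf(amps, metrics[[m]])
    data.frame(metric = m, slope = fit$slope, intercept = fit$intercept,
               vaf = fit$vaf, n = fit$n)
  }))
}

# phase-binned step-height profile across all stimulated sessions
pipeline_phase_profile <- function(sessions, amps) {
  stim_names <- paste0("amp_", round(amps))
  rows <- list()
  for (nm in intersect(stim_names, names(sessions))) {
    s <- sessions[[nm]]
    if (nrow(s$stims) == 0) next
    rl <- timeline_event_times(s$timeline, "right", "lift")
    ph <- stimulus_phase(s$stims$onset_s, rl)
    ev <- split_events(s$events_truth)
    cyc <- segment_cycles(ev$right, "right")
    kin <- s$kinematics
    vals <- vapply(seq_len(nrow(ph)), function(i) {
      k <- which.min(abs(cyc$lift_s - ph$onset_s[i]))  # cycle owning the lift
      step_height(cyc[k, ], kin$time_s, kin$right_mtp5_y_cm)
    }, numeric(1))
    rows[[nm]] <- list(ph = ph, vals = vals)
  }
  if (length(rows) == 0) {
    return(phase_binned_effects(
      data.frame(onset_s = numeric(0), phase = numeric(0),
                 offset_s = numeric(0), phase_coherent = logical(0),
                 excluded = logical(0)), numeric(0)))
  }
  ph <- do.call(rbind, lapply(rows, `[[`, "ph"))
  vals <- unlist(lapply(rows, `[[`, "vals"))
  phase_binned_effects(ph, vals)
}

# the pre-registered comparison: no stimulation vs maximum amplitude
pipeline_tests <- function(cycles, session_names, amps) {
  if (length(amps) == 0) return(NULL)
  max_name <- paste0("amp_", round(max(amps)))
  a <- cycles[cycles$session == max_name & cycles$limb == "right",
              "step_height_cm"]
  b <- cycles[cycles$session == "spontaneous" & cycles$limb == "right",
              "step_height_cm"]
  if (length(a) < 3 || length(b) < 3) return(NULL)
  res <- select_and_run_test(a, b, paired = FALSE, alternative = "greater")
  data.frame(comparison = "max stimulation vs spontaneous (right step height)",
             test = res$test, p = res$p, statistic = res$statistic)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  w(report$cycles, "cycles.csv")
  w(report$emg_metrics, "emg_metrics.csv")
  w(report$fits, "fits.csv")
  w(report$phase_profile, "profile.csv")
  w(report$tests, "tests.csv")
  w(report$asymmetry, "asymmetry.csv")
  w(report$stim_log, "stims.csv")
  jsonlite::write_json(report$provenance, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.cg_report <- function(x, ...) {
  cat("<cg_report>\n")
  cat(sprintf("  sessions: %s\n", paste(unique(x$cycles$session),
                                        collapse = ", ")))
  if (!is.null(x$fits)) {
    cat("  dose-response fits:\n")
    for (i in seq_len(nrow(x$fits))) {
      cat(sprintf("    %-20s slope %.4g  VAF %.1f%%\n", x$fits$metric[i],
                  x$fits$slope[i], x$fits$vaf[i]))
    }
  }
  if (!is.null(x$tests)) {
    cat(sprintf("  %s: %s, p = %.3g\n", x$tests$comparison, x$tests$test,
                x$tests$p))
  }
  invisible(x)
}
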