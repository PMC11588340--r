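Package: corticogait
Title: Phase-Coherent Cortical Stimulation and Locomotor Analysis for Spinal Hemisection Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of closed-loop, EMG-triggered intracortical
    microstimulation during rodent treadmill locomotion after a lateral spinal
    hemisection. Provides a seeded synthetic-session generator (hindlimb marker
    kinematics, flexor and extensor EMG envelopes, stimulation event tables,
    motor-map and evoked-rhythm ground truths), an emulated real-time
    phase-coherent stimulation controller (causal online envelope, threshold
    trigger, delayed biphasic trains), gait-cycle segmentation with the standard
    treadmill metrics (step height, flexion velocity, swing and stance asymmetry
    indices, posture, dragging), EMG burst quantification, awake motor-map
    summaries (threshold search, map size, joint population maps, ipsilateral
    dominance), evoked-rhythm classification, behavioral scores (ladder
    foot-fault, injury severity classes, 20-point open-field scale), and a
    statistical layer: dose-response linear fits with variance accounted for,
    phase-binned effect profiles, normality-gated test selection, and paired
    t-test power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
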