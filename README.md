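# corticogait

Closed-loop phase-coherent cortical stimulation and locomotor analysis for
rodent spinal-hemisection studies — as a fully synthetic, testable pipeline.

## The problem

After a lateral thoracic hemisection (T9), rats show a characteristic
hemiparetic gait on the treadmill: the ipsilesional (left) hindlimb loses
support and extension, swing durations become asymmetric (ipsilateral swing
dominance around 29%, contralateral stance dominance around 16%), the
ipsilesional ankle extensor burst collapses (about −72% duration, −92% total
activation), posture drops and the toe drags. Short intracortical
microstimulation trains (40 ms, 330 Hz) delivered through a 32-channel array
in the ipsilesional motor cortex, timed within ±75 ms of the contralateral
foot lift ("phase coherence"), immediately counteract these deficits, with
effect sizes that grow linearly with stimulation amplitude. Longer trains
(250 ms) can recruit bilateral alternating locomotor-like rhythms.

`corticogait` re-implements the full measurement chain behind such
experiments for simulation studies and method validation:

- **Synthetic sessions** (`simulate_session()`): programmed gait event
  timelines with per-limb stance/swing structure, six sagittal markers per
  hindlimb at 119.2 Hz, four EMG envelopes (left/right tibialis anterior and
  medial gastrocnemius) at 6 kHz, injury severity presets, and a hidden
  `truth` record for every parameter.
- **Closed-loop controller** (`run_closed_loop()`): causal moving-RMS
  envelope, manual-threshold trigger with refractory, fixed delay, biphasic
  train scheduling — streamable in chunks with bit-identical output.
- **Gait kinematics** (`detect_gait_events()`, `compute_cycle_metrics()`):
  contact/lift detection, cycle segmentation, step height
  (max swing − mean stance elevation), flexion velocity, swing/stance
  asymmetry indices `1 − (left/right)` (with the ipsi-positive reporting
  convention), posture (iliac crest height), dragging index, stimulus phase.
- **EMG quantification** (`detect_bursts()`, `total_activation()`,
  `cycle_normalized_envelope()`): burst duration and integral, baseline
  normalization, phase-averaged envelopes.
- **Awake motor maps** (`find_threshold()`, `map_size()`,
  `joint_population_map()`, `ipsilateral_dominance()`): descending threshold
  search from 100 µA, responding-site counts, population modal maps,
  longitudinal trajectories.
- **Rhythms and behavior** (`classify_rhythm()`, `ladder_score()`,
  `classify_severity()`, `openfield_score()`): alternation counting, ladder
  paw-placement percentages, severity classes, the 20-point open-field
  locomotor scale.
- **Statistics** (`linear_fit_vaf()`, `phase_binned_effects()`,
  `select_and_run_test()`, `power_paired_t()`): dose–response lines with
  VAF = 100·(1 − SS_res/SS_tot), phase-binned effect profiles,
  normality-gated one-sided test selection, and noncentral-*t* power
  analysis with a Monte-Carlo cross-check.

The stimulation-effect model is phenomenological: each train at amplitude
*A* and offset Δ from the contralateral lift multiplies the affected cycle's
contralateral step height, flexion velocity, ipsilesional crest height and
extensor burst amplitude by `1 + g·(A − A_min)·K(Δ)`, where the kernel *K*
is 1 inside the ±75 ms coherence window and decays to 0 as a raised cosine
over one further half-width.

## Worked example

```r
library(corticogait)

session <- simulate_session(gait_model_params(), injury_params("moderate"),
                            n_cycles = 15, seed = 42)
session
#> <cg_session: 15 cycles, 12.6 s, injury 'moderate', 0 stim trains>
#>   kinematics: 1507 frames @ 119.2 Hz; EMG: 75833 samples @ 6000 Hz

metrics <- compute_cycle_metrics(session)
session_asymmetry(metrics)$swing
#> [1] 0.2694  # ipsilateral swing dominance recovered near the programmed 0.29

# tune the trigger delay so trains land on the contralateral foot lift
probe <- run_closed_loop(session, trigger_config("iTA", threshold = 0.2,
                                                 delay = 0))
lifts <- subset(session$events_truth, limb == "right" & event == "lift")$time_s
tune_delay(probe$log$trigger_s, lifts)
#> [1] 0.406  # seconds from flexor-burst trigger to the next right lift

# full experiment: amplitude sweep, metrics, dose-response fits, test
report <- run_pipeline(pipeline_config(seed = 42, n_cycles = 15))
report
#> <cg_report>
#>   sessions: intact, spontaneous, amp_30, amp_70, amp_110, amp_150
#>   dose-response fits:
#>     step_height          slope 0.01988  VAF 100.0%
#>     flexion_velocity     slope 0.2294  VAF 98.3%
#>     posture              slope 0.007992  VAF 100.0%
#>     extensor_activation  slope 7.967e-05  VAF 100.0%
#>   max stimulation vs spontaneous (right step height): unpaired t, p = 1.63e-41

power_paired_t(2.5, 5)   # study design: effect 2.5 SD, n = 5 pairs
#> [1] 0.9975
```

The step-height slope of ~0.0199 cm/µA against a ~2 cm baseline recovers the
programmed fractional gain of 0.01 per µA; the spontaneous injured session
shows the programmed swing dominance while the stimulated sessions reverse
it in proportion to amplitude.

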