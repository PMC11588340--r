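---
title: "Phase-coherent cortical stimulation and locomotor quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coherent cortical stimulation and locomotor quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticogait)
```

`corticogait` couples a seeded synthetic-data generator for rodent treadmill
locomotion after a lateral spinal hemisection with the complete analysis
chain used in closed-loop cortical-neuroprosthesis experiments. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the package's tests can and cannot establish about real data.

Throughout, *ipsilateral* means the left side — the side of both the
implanted motor cortex and the hemisection — and *contralateral* the right.

## The gait model

A locomotor bout is a sequence of gait cycles with a shared period (default
0.8 s, a typical stride time for a rat walking at 23 cm/s), the right limb
offset by half a cycle. Each cycle is split into stance (foot contact to
lift) and swing (lift to next contact). Intact animals use the per-limb duty
cycles (default 0.65).

Injury timing deficits are expressed as two dominance ratios:
`swing_dominance_ipsi` = SwLeft/SwRight − 1 and `stance_dominance_contra` =
StRight/StLeft − 1. A point worth making explicit: once both limbs share a
cycle period *T*, these two ratios pin down all four phase durations
uniquely,

SwRight = d_st · T / ((1 + d_st)(1 + d_sw) − 1),

so a swing excess on one side *forces* a stance excess on the other. The
constructor therefore rejects configurations with exactly one non-zero
dominance — they are geometrically unrealisable — and the severity presets
specify both together (moderate: 0.29 and 0.16, the deficits typical one
week after hemisection). Per-cycle duration jitter (default 2% SD) scales
all phases of a cycle jointly, so the programmed ratios are preserved
exactly in expectation and almost exactly per cycle.

Marker trajectories follow a deliberately simple geometry: during stance the
foot sits at its resting height and travels backwards at belt speed; during
swing it follows a half-sine vertical arc of the programmed step height with
linear forward progression. The half-sine was chosen because it is smooth,
single-peaked, and has a closed-form peak ascending velocity, πh/T_swing,
which the flexion-velocity estimator must recover — a useful analytic
oracle. Six markers are generated per hindlimb (iliac crest, trochanter,
knee, ankle, fifth metatarsal, fourth toe tip). Only three carry
information: the fifth metatarsal drives event detection, step height and
flexion velocity (it is the foot marker least affected by toe drag), the
fourth toe drives the dragging index, and the iliac crest drives posture.
The remaining markers are fixed segment offsets kept for schema
completeness. The marker set lists five canonical anatomical names plus the
ankle, which we include as the sixth marker.

Two secondary modelling choices deserve a note:

- **Toe snap-off.** The dragging index counts swing samples within a
  tolerance band (0.2 cm) of the ground. A smooth arc spends a predictable
  extra ~5% of swing inside that band at take-off and landing, which would
  bias the drag round-trip. The generated toe therefore *snaps* 0.25 cm
  above rest the moment it leaves the ground — which is also how a dragging
  toe behaves once released. With this, the measured index tracks the
  programmed `drag_fraction` to within ±0.05 at default noise.
- **Extensor burst reference.** The impaired ipsilesional extensor (iMG)
  burst occupies `extensor_burst_duration_scale` of the *intact* stance
  duration (duty cycle × period), not of the injured stance, and its
  amplitude is rescaled so the burst integral scales by
  `extensor_activation_scale`. Deficits are defined against the pre-injury
  baseline, so normalising an injured session by an intact one recovers the
  programmed −72%/−92% exactly rather than confounded by the altered
  stance duration.

Noise is additive Gaussian everywhere (0.05 cm on markers — the order of
pose-estimation error after curation — and 0.01 mV on EMG envelopes,
rectified at zero). This is the simplest model with a controllable SNR; it
has no outliers, no marker swaps, no motion artefacts, which is exactly why
round-trip tests passing here do not certify the detectors against real
video tracking (see *Limitations*).

## The stimulation-effect model

Stimulation effects are phenomenological, not biophysical. Each train at
amplitude *A* (µA) and signed offset Δ from the nearest contralateral foot
lift multiplies four quantities of the cycle owning that lift by
`1 + g · max(0, A − amp_min) · K(Δ)`:
contralateral step height (`gain_step_height`, default 0.01/µA),
contralateral flexion velocity (via an advance of the swing-arc peak),
ipsilesional crest height, and ipsilesional extensor burst amplitude.
Amplitudes at or below `amp_min` (the bottom of the functional range,
default 30–150 µA) do nothing.

The kernel *K* is 1 for |Δ| ≤ 75 ms — the phase-coherence window — and
decays to zero as a raised cosine over one further half-width. A plateau was
chosen over a pure raised cosine so that "inside the coherence window"
means the full effect, matching how coherence is defined as a binary
criterion, while still giving a smooth falloff rather than a cliff for
near-miss trains. Effects apply to the single cycle containing the
reference lift; carry-over to later unstimulated cycles is deliberately not
modelled (40 ms trains act on the ongoing swing preparation), so the
generator makes the strongest testable assumption rather than a vaguer one.

Because step height and flexion velocity share the swing arc, the velocity
inherits the step-height gain multiplicatively; the dedicated velocity gain
additionally advances the arc peak. Recovery tests therefore isolate gains
one at a time, or recover the step-height gain from the height fit and the
velocity gain from the velocity/height ratio.

## The closed-loop controller

The controller emulates the real-time chain: a causal moving-RMS envelope
(20 ms window — the processing details of the original online system are
not public, so this is an explicit stand-in with the right causality), a
manually chosen threshold (a helper suggests mean + 3 SD of a quiet
baseline, but it is never applied silently), a refractory period (default
250 ms, below any plausible cycle duration, giving one trigger per gait
cycle), a fixed delay, and biphasic train scheduling with
`n_pulses = floor(duration × rate)` so a train never exceeds its stated
duration (13 pulses for 40 ms, 82 for 250 ms at 330 Hz).

The implementation is vectorised but maintains an explicit carried state
(trailing window buffer, last trigger time), so a stream may be cut at any
sample and processed in chunks with bit-identical output — the property that
makes "causal" testable: truncating the input after time *t* never changes
any output at or before *t*.

With the flexor-triggered protocol, the trigger fires at the ipsilateral
flexor burst onset (the left lift); `tune_delay()` measures the median
interval to the next right lift and in synthetic sessions delivers well over
90% of trains inside the ±75 ms window. The tuned delay (~0.4 s at the
default 0.8 s cycle) is longer than the 140–190 ms used experimentally
because the real trigger threshold crosses mid-burst and real cycles are
shorter; the controller contract is the same.

## Event detection and cycle metrics

The gait event detector works on the vertical fifth-metatarsal trace:
a 3-frame moving average, a ground estimate (20th percentile), a coarse
swing mask (ground + 0.12 cm, debounced at 50 ms), and then a sub-frame
refinement of each edge: the contiguous arc flank between 0.1 and 0.5 cm
above ground adjacent to the edge is fitted with a line and extrapolated to
ground level. The flank must be *contiguous with the edge* — selecting any
window sample in that height band occasionally captured stance noise and
produced 100 ms outliers. Extrapolating a chord of the half-sine onset
carries a sub-millisecond analytic bias. At zero noise every event lands
within one frame of the programmed truth; at default noise ≥95% land within
two frames.

Cycle metrics follow the standard definitions: step height = max swing
elevation − mean stance elevation (translation-invariant by construction);
flexion velocity = max finite-difference vertical velocity from lift to the
swing apex; posture = mean crest height over the cycle, optionally as % of
an intact baseline; dragging = fraction of swing with the toe within
tolerance of ground. The asymmetry indices are the literal
`1 − (left/right)` of phase durations; because the figure convention
"positive = ipsilateral dominance" has the opposite sign for swing, both
are exposed: the ipsi-positive value is returned by default and the literal
value always rides along as an attribute, so no information is discarded.
Per-trial values average per-cycle metrics (rather than normalising first);
with 10–20 cycles the difference is far below the reported tolerances.

## EMG quantification

Bursts are maximal intervals where the envelope stays above 20% of the
recording's 95th-percentile level, after fusing sub-threshold gaps shorter
than 10 ms and discarding intervals under 30 ms — standard locomotor-EMG
criteria, all configurable. Total activation integrates the envelope over
the detected burst (trapezoidal), matching the burst-centred framing of the
deficit quantification; integrating the whole cycle instead changes the
absolute numbers but not the normalised ratios. Rhythm classification adds
an absolute peak floor (pre-train baseline mean + 4 SD, and at least 1.5×
the baseline maximum) so that a quiescent sedated recording classifies as
"none" instead of promoting noise excursions to bursts — a purely relative
threshold has no defence against that.

A "complete repetition" of an evoked rhythm is one burst followed by one
burst on the opposite side (order-agnostic start), counted by greedy
pairing; overlapping left/right bursts are flagged `bilateral_non_alternated`
rather than counted. The repetition unit is configurable in interpretation
but fixed in code, since the printed 1X/2X/3X counts do not define it.

## Motor maps

Threshold search descends from 100 µA in 10 µA steps to a 10 µA floor,
stopping at the first non-response — the minimal procedure consistent with
"minimum amplitude evoking a visible twitch" plus an interruption rule. The
step size is not documented experimentally; 10 µA makes the search grid
explicit and testable against an exhaustive scan. Sites still responding at
the floor are clamped and flagged. In synthetic mode the twitch oracle is
monotone by construction (evoked peak > 4 noise SD within 60 ms).

The population joint map takes the per-site modal (category, side) pair;
ties resolve by the declared priority distal > proximal > none and
bilateral > contra > ipsi, always flagged — determinism is worth more than
any particular tie convention. Scenario multipliers for the generator
(day 5: ipsi ×0.10, contra ×0.47; week 2: ×1.95/×3.64; week 8: ×2.15/×3.50
of the intact responding fractions, intact default 0.25 per side) encode the
longitudinal transmission course: the early bilateral collapse (−90%/−53%),
the contralateral expansion consolidating around +250%, and the chronic
ipsilateral increase around +115% with most of the rise in weeks 1–2. On a
32-site grid these fractions quantise to whole sites (e.g. day-5 ipsilateral
−87.5% rather than −90%).

## Statistics

The dose–response adequacy measure is VAF = 100·(1 − SS_res/SS_tot) about
the mean of y — the standard "variance accounted for"; a response with zero
variance is reported as a flat perfect fit and flagged degenerate rather
than producing 0/0. Test selection mirrors the study's procedure: a
one-sample Kolmogorov–Smirnov test on each standardised sample (α = 0.05;
the level and standardisation are our explicit choices, since only the test
is documented) gates t-test vs Wilcoxon, paired or unpaired by design, and
every test is one-sided in the pre-declared improvement direction.
Trivially non-normal samples (zero-inflated dragging) can bypass the gate
with `force_nonparametric`. No multiplicity correction is applied: the
design pre-registers a single no-stimulation versus maximum-stimulation
comparison per figure.

Power for the one-sided paired t-test uses the noncentral *t* distribution
with noncentrality d·√n and n − 1 degrees of freedom; the Monte-Carlo route
simulates normal paired differences and agrees within ±0.01 at 10⁵
replicates. The two design points — effect 2.5 SD with n = 5 (when
replicates are animals) and 1.5 SD with n = 7 (when replicates are gait
cycles) — both exceed 0.8:

```{r power}
power_paired_t(2.5, 5)
power_paired_t(1.5, 7)
```

The pilot-study power figures of 97%/99% rest on an effect size that is
ambiguous as printed, so they are not reproduced as checks.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use sessions of 12–20 cycles
(10–17 s of locomotion), 4-level amplitude sweeps, and 10⁵ Monte-Carlo
power replicates — sizes at which every recovery tolerance is comfortably
resolved while the whole suite runs in about a minute. Every source of
randomness flows from one integer seed, fanned out deterministically per
stage; the same (configuration, seed) pair reproduces every table bit for
bit, and generators restore the caller's RNG state.

## Limitations

- The generator emulates the *statistical* structure the analyses assume —
  programmed asymmetries, burst scalings, linear phase-gated effects,
  Gaussian noise. It does not emulate marker swaps, occlusions, tracking
  outliers, EMG crosstalk or movement artefacts; detector performance here
  is an upper bound on real-data performance.
- Stimulation effects are single-cycle and multiplicative; any carry-over,
  adaptation or fatigue is out of scope.
- No musculoskeletal or neural-circuit simulation: ketamine sedation is
  modelled only as "rhythm generation disabled", cortical ablation only as
  a generator flag; raw (unrectified) EMG is not synthesised — envelopes
  are the interchange format.
- Behavioral scores (ladder counts, open-field sub-scores) are inputs, not
  derived from video.
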