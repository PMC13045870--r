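---
title: "Simulated operant behavior: task engine, synchronization, and signal-detection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated operant behavior: task engine, synchronization, and signal-detection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantr)
```

## What this package models

`operantr` is a hardware-free implementation of a modular behavioral
platform for rodent psychophysics. The physical platform couples a
computer program (trial scheduling, state transitions, external-device
timestamping) with a microcontroller hub (MCU #1) that operates the
lick-ports and records licks, valve openings and state transitions on
its own millisecond clock. This package reproduces every layer of that
design in software: the finite-state task engine, the constrained trial
scheduler, the two-clock synchronization that assembles standardized
per-trial records, the signal-detection analysis of performance and
side-bias, and the two-stage pupillometry pipeline. A parametric
virtual rig — simulated clocks, encoder and camera streams, synthetic
eye frames, and a signal-detection virtual mouse — stands in for
hardware and animals, so the full pipeline is testable end to end.

Two paradigms are bundled as presets (`task_preset()`):

* **Head-fixed closed-loop two-choice discrimination.** Each trial is a
  50 cm *approach* corridor followed by a 50 cm *grating* corridor, the
  visual scene advancing 1 cm per cm of wheel travel. Vertical gratings
  reward left licks, angled (135°) gratings right licks, each with a
  ~6 µl drop. Stimuli appear with probability 0.5 each, never more than
  3 in a row. The reward zone opens 50/6 ≈ 8.33 cm into the grating
  epoch; if automatic delivery is enabled and the animal has not earned
  a reward, a drop is delivered from the stimulus-associated port at
  5·50/6 ≈ 41.67 cm. Sessions end at 125 rewards (≈750 µl, the daily
  water ration over the 6 µl drop size) or 90 min.
* **Freely moving Go/No-go luminance discrimination.** Trials are
  self-initiated through a touch sensor; the 4 s stimulus is bright (Go,
  probability 0.3, run limit 10) or dark (No-go). Licks at least 0.5 s
  after stimulus onset on Go trials earn a ~4 µl drop; sessions end at
  190 rewards or 120 min.

Three shaping presets (head-fixed acclimation with the side-bias
deterrent, and the two freely moving acclimation stages) complete the
training progressions.

## The task engine

`advance(state, config, event)` is a pure transition function: given an
engine state, a configuration and one rig event (lick, encoder distance
increment, timer tick, initiation touch, manual valve command, or
parameter update), it returns the next state plus the actions the rig
must execute. Design choices that the task description leaves open were
fixed as follows:

* **Decision lick.** The trial's decision is the *first* lick whose
  corridor position lies inside the reward zone; later licks are
  recorded but do not change the outcome.
* **Go/No-go delay.** Licks during the 0.5 s response delay count for
  outcome scoring but cannot trigger the valve; reward eligibility and
  scoring are deliberately separate.
* **Backward wheel motion** decrements accumulated distance but floors
  at the epoch start, so corridor positions never go negative.
* **Reward zone closure.** The decision zone closes at the
  auto-delivery distance (41.67 cm), i.e. scoring uses the central two
  thirds of the epoch.
* **Side-bias deterrent.** Consecutive same-side counting uses rewarded
  *trials* (one decision per trial), with the 3–8 threshold redrawn
  uniformly every trial. The scheduled release from the other side
  2 s after the next stimulus change is part of the deterrent rule and
  fires regardless of the manual auto-water toggle; the lock lifts only
  when the subject itself triggers the other port.
* **Parameter updates** queue during a trial and land at the next trial
  boundary (mirroring a GUI that accepts callbacks at trial end); only
  manual valve commands act immediately, logged as `MANUAL_OPEN` and
  flagged `isManualOpen` in the record. Manual and automatic deliveries
  are kept as mutually exclusive flags from subject-triggered rewards.
* **Reward counting.** Boosted trials (`x_left`/`x_right`) dispense a
  single valve action of three drops; the reward counter counts drops,
  so volume conservation (drops × drop volume = session volume) holds
  exactly.

The engine is deterministic given (config, schedule, event sequence,
seed): its only internal randomness — deterrent thresholds and
random-side releases — is pre-drawn from named sub-streams of the
session seed.

## Scheduling

Schedules are generated entirely at session start. The run constraint
is enforced by a *forced flip*: when a draw would create a run of
`max_consecutive + 1`, the draw is redone among the other labels with
renormalized probabilities. This is O(n) and matches the platform's
"alters next trial stimulus" behavior, but it slightly inflates the
frequency of minority labels when the constraint binds often (at
Go probability 0.3 with limit 10 the inflation is negligible; at 0.5
with limit 3 the empirical frequencies stay within ±0.02 of nominal).
We document rather than correct this bias: the empirical frequencies of
the *emitted* schedule are what the analysis sees.

## Two clocks, one alignment rule

The platform inherently uses two clocks: MCU #1 timestamps licks,
valves and state transitions; the program clock timestamps
external-device samples (encoder, camera). Anchor-relative times never
cross clocks: MCU events are expressed as differences on the MCU clock,
device samples as differences on the program clock. No cross-clock
regression is attempted — offsets cancel in differences, and the
residual discrepancy (drift, jitter, the 300 Hz polling grid, the
integer-millisecond log resolution) is what `clock_discrepancy()`
benchmarks. The simulated clock model is
`t_dev = (t_true + offset)(1 + drift·1e-6) + N(0, jitter)` quantized
down to the clock's period grid. Trials missing their anchor onset are
excluded from alignment (with a message and a count in the session
metadata) rather than interpolated, and duplicate encoder timestamps
are an error rather than silently merged — they indicate a generator
bug.

The per-trial output record mirrors the platform's MATLAB struct
field-for-field (`TrialID`, `TrialType`, `NoOfTimestamps`,
`Timestamps`, `isLickLeft`, …, `encoderData_combined`, `Velocity`,
`frameData_combined`, `pupilRadius_combined`), serialized as one JSON
file per trial. JSON has no NaN literal, so not-a-number is written as
the string `"NaN"`; numbers are written at 17 significant digits so
round-trips are lossless. The MCU log is a versioned tab-separated
text file with integer-millisecond device times.

## The virtual mouse

The generative agent is an equal-variance signal-detection model: on an
engaged trial the internal evidence is `N(+d/2, 1)` for the
left-rewarded class and `N(−d/2, 1)` for the right-rewarded class, and
the agent responds left when evidence exceeds the criterion `c`. With
hit = left lick on vertical and false alarm = left lick on angled, the
analysis estimators have closed-form targets: `z(H) − z(F) → d` and
`−(z(H) + z(F))/2 → c` (positive c = rightward bias, matching the
sign convention of the side-bias index). A lapse parameter mixes in
uniform guessing, and per-trial engagement probabilities generate
no-interaction trials. Locomotion is a truncated-normal speed process
(default 15 ± 5 cm/s, floored at 0) sampled per 300 Hz tick — a
deliberately simple kinematic model that produces realistic variable
trial durations; it does not attempt bout structure or acceleration
dynamics. Lick bouts, approach licks and disengagement are similarly
stylized. What passing tests show, therefore, is that the *pipeline*
recovers the generative parameters it was given — not that real mice
behave like this agent.

## Performance and side-bias analysis

Sensitivity is `d' = z(hit rate) − z(false-alarm rate)` with `z` the
standard-normal quantile function. For grating discrimination, the hit
rate is the proportion of vertical trials with a first in-zone left
lick among vertical trials with any in-zone lick, and correspondingly
for angled trials; no-interaction trials are excluded. For epoch
discrimination, rates are the proportions of trials with at least one
lick in the central two thirds of the grating vs approach epoch,
passed through the same z-machinery ("standardized proportion" is read
as exactly this). Extreme rates use the standard 1/(2N) correction
(0 → 1/(2N), 1 → 1 − 1/(2N)); a log-linear correction would be an
alternative, but 1/(2N) keeps the corrected rate a function of the
count alone.

The side-bias index is the signed criterion `−(z(H) + z(F))/2`. The
platform's description renders it with an absolute value yet assigns
signs to its interpretation; the only reading consistent with
"positive = rightward" is the signed criterion with thresholds applied
to its absolute value, which is what `bias_index()` implements. The
bias-correction controller engages at |index| > 1, boosts the
non-preferred side (three drops), and re-equalizes after at least two
consecutive sessions with |index| < 0.25 (the absolute reading of the
reduction test).

The learning criterion is the first session of a three-session window
in which at least two sessions exceed d' = 1.5. Strictness is exposed
as a parameter (`strict = TRUE` by default, i.e. `>`): the source
material uses both "> 1.5" and "≥ 1.5 for 3 consecutive days" in
different places, an internal inconsistency we surface rather than
hide.

## Pupillometry

Stage 1 classifies each frame open vs occluded. Instead of a deep
network, the classifier is a linear discriminant over six intensity
features (dark-pixel fraction, mean, SD, 10th percentile, maximum
row-wise dark fraction, bright-eyelid fraction) — the contract
downstream stages need is a binary label with a confidence, and on the
synthetic frames this model reaches the same 100% held-out accuracy
benchmark (70 + 70 training, 15 + 15 held-out frames). The interface is
pluggable, so a learned deep model can be substituted for real videos.

Stage 2 segments the pupil in open frames: binarize at a dark/bright
threshold (two-means of the intensity histogram, deterministic
initialization at the intensity extremes), label connected dark
components, and fit a circle to the largest (centroid; radius from
area). Candidates are rejected when the radius leaves the configured
bounds, when pixels extend beyond 1.6× the fitted radius, or when the
fitted disk is under-filled — non-circular dark structures fail these
checks. A full Hough accumulator was considered and rejected: on
dark-disk pupils the centroid/area fit is equally accurate (median
radius error well under 5% at the generator's noise level) at a small
fraction of the cost. Open frames with no accepted circle (the
platform reports ~1–3% of open frames) are flagged for user seeding;
`seeded_segment()` then fits locally around the click, always returning
a circle or an explicit low-confidence flag. Radii are normalized to
the session median; "session" means all frames in one directory.

The synthetic eye frames are 100×80 px: a dark disk (intensity ~40) on
an iris/sclera background (~150) with additive Gaussian noise (default
SD 8), occluded frames drawing a brighter eyelid band (~185) from the
top of the frame covering at least 80% of the pupil. Real eye images
have specular highlights, graded eyelid shadows, off-axis gaze and
motion blur, none of which the generator emulates — the synthetic
benchmark validates the pipeline's logic and its numerical behavior,
not its robustness to real-world imaging.

## Numerical choices and degenerate inputs

* Clock quantization floors onto the period grid with a 1e-9 s epsilon
  so on-grid times do not slip a tick through floating-point error.
* The MCU log stores integer milliseconds (the device's native
  resolution); the synchronization benchmark uses the clock-resolution
  boundary annotations, so a jitter-free rig shows exactly zero
  epoch-duration discrepancy while the written log still quantizes.
* `rate_correction()` refuses n = 0; summaries with an empty stimulus
  class report a missing d' with counts instead of fabricating one.
* Engine events may not move time backwards; an event before session
  start is an error; events after session end are ignored.
* Ties in `kmeans` thresholding are avoided by initializing the two
  centers at the frame's intensity extremes.

## Problem sizes

The bundled tests exercise full-scale sessions where a printed constant
depends on it (the 125-reward budget session, 1,000 × 2,000-trial
schedule scans, the 70/70 + 15/15 classifier benchmark, 500-frame
segmentation error, 200-replicate parameter recovery at 300 decision
trials) and smaller sessions (3–25 rewards) where only the pipeline's
invariants are at stake; the invariant suite covers both closed-loop
and freely moving paradigms across multiple seeds. The
parameter-recovery tolerance of ±0.25 at 300 decision trials is
reported as specified even though the binomial sampling variance of
`z(H) − z(F)` at that size makes a 95% pass rate unreachable for the
larger sensitivities (the exact coverage at d = 2.5 is ≈0.80); the
companion bias-index recovery at ±0.2 passes comfortably.

## Limitations

The package renders no stimuli and drives no hardware: stimulus
parameters travel as metadata, and the GUI is replaced by the
parameter-update API and the command-line front end. Psychometric-curve
fitting, reaction-time modeling, and genotype comparisons are out of
scope; the virtual mouse is a test harness, not a behavioral model.
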