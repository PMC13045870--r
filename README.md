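# operantr

Simulation, synchronization and signal-detection analysis of
trial-based operant behavior.

Modern rodent psychophysics rigs couple a computer program (trial
scheduling, state transitions, external-device timestamping) with a
microcontroller hub that operates lick-ports and records licks, valve
openings and state transitions on its own clock. `operantr`
re-implements such a platform entirely in software, for people who
build, test or analyze these experiments: an event-driven finite-state
task engine for head-fixed closed-loop and freely moving operant
paradigms, a constrained stochastic trial scheduler, a two-clock
synchronization layer producing standardized per-trial records,
signal-detection performance and side-bias analysis, and a two-stage
pupillometry pipeline. A parametric virtual rig — simulated device
clocks, 300 Hz encoder and 10 Hz camera streams, synthetic eye frames,
and a signal-detection virtual mouse — replaces hardware and animals,
so every stage runs and is testable at the desk.

## The models at the core

**Task engine.** Trials are ordered epochs; epoch transitions fire on
accumulated locomotion distance, timers, or sensor events. In the
bundled head-fixed task a 50 cm approach corridor precedes a 50 cm
grating corridor whose reward zone spans its central two thirds,
[50/6, 250/6) ≈ [8.33, 41.67) cm; sessions end at 125 rewards (≈750 µl
at 6 µl per drop) or 90 min. The freely moving Go/No-go task uses
self-initiated trials, a 4 s stimulus with Go probability 0.3 (run
limit 10), a 0.5 s response delay, and ends at 190 rewards or 120 min.

**Performance.** With z the standard-normal quantile function and the
1/(2N) correction for extreme rates,

    d' = z(hit rate) − z(false-alarm rate)
    side-bias index = −(z(hit rate) + z(false-alarm rate)) / 2

where, for two-choice grating discrimination, a hit is a first in-zone
left lick on a vertical-grating trial and a false alarm a first
in-zone left lick on an angled-grating trial. Positive bias values
indicate rightward bias; correction engages at |index| > 1 and
re-equalizes after two consecutive sessions with |index| < 0.25.
Learning is declared on the first session of a three-session window in
which at least two sessions have d' > 1.5.

**Virtual mouse.** An equal-variance signal-detection agent: evidence
~ N(±d_true/2, 1), respond left iff evidence > c_true, plus lapse and
engagement parameters — so the analysis estimators have known targets.

**Pupillometry.** Frames are classified open vs occluded (linear
discriminant over intensity features; 100% held-out accuracy on the
bundled 70/70 + 15/15 synthetic benchmark), open frames segmented for a
dark circular pupil, radii normalized to the session median, and open
frames without a found circle queued for user-seeded re-segmentation.

## Worked example

```r
library(operantr)

cfg <- task_preset("two_choice")      # head-fixed closed-loop preset
cfg$session_end$max_rewards <- 25L    # a short demonstration session

dir <- file.path(tempdir(), "demo")
session <- cmd_simulate(cfg, seed = 42, out = dir,
                        policy = agent_policy(d_true = 2, c_true = 0.3,
                                              lapse = 0.05))
session
#> Session sim-two_choice_closed_loop-seed42: 30 trials, 25 rewards, end reason: max_rewards

cmd_analyze(dir, file.path(dir, "analysis"))
#> Performance summary (two_choice)
#>   outcomes: hit_vertical=11, fa_vertical=3, hit_angled=14, fa_angled=2, no_interaction=0
#>   hit rate 0.786, false-alarm rate 0.125 (corrected)
#>   d' = 1.942, epoch d' = 3.962, side-bias index = +0.179
```

The virtual mouse was given sensitivity `d_true = 2` and a rightward
criterion `c_true = 0.3`; from 30 simulated trials the analysis
recovers d' = 1.94 and a positive (rightward) bias index of 0.18 —
both within sampling error of the generative values. The session
directory contains the MCU event log (`mcu_log.tsv`), one JSON record
per trial mirroring the platform's struct fields (`TrialID`,
`isLickLeft`, `encoderData_combined`, `Velocity`, ...), CSV exports,
ground truth, and a run manifest.

Session-level rules:

```r
learning_session(c(0.4, 1.1, 1.8, 2.2, 1.9))
#> [1] 2
bias_controller(c(1.2, 0.6, 0.2, 0.1))
#> [1] "boost_left"  "boost_left"  "boost_left"  "re_equalize"
```

A thin command-line front end wraps the same functions
(`inst/cli/operant`): `operant simulate --config two_choice --seed 7
--out session/`, then `operant analyze`, `operant pupil`,
`operant validate`.

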