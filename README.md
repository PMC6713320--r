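# sonolift

Offline analysis toolkit for a **music-based biofeedback system for the
barbell deadlift**. During a lift, two technique faults raise injury risk:
losing spinal midline stability (forward flexion under load) and letting the
bar drift forward of the mid-foot. A sonification rig punishes both in real
time — spine flexion degrades the music's effective sample rate ("metallic"
distortion), bar drift collapses an immersive speaker array down to a narrow
frontal image — so the lifter is steered by reward and punishment rather
than verbal cues. `sonolift` re-implements the measurement, mapping and
evaluation chain of such a system as a testable offline package for
movement scientists: it is not a real-time audio engine.

## What it computes

From labelled 3D marker trajectories (mm, 100 Hz) it derives, per frame:

- **spine bend** — the length of the vertebral marker chain
  L4–T12–T7–C2: `d0 + d1 + d2`, the sum of consecutive Euclidean
  distances. Forward flexion stretches the chain.
- **barbell–foot distance (B-F)** — the horizontal distance between the
  line through the barbell extremities and the nearer of the two
  front-of-foot markers, signed (negative once the bar passes the toes).

Per-athlete static calibrations (neutral spine, instructed maximal bend,
setup bar position) turn these into non-dimensional forms

```
sb  = (spinebend − neutralspine) / (maxspinebend − neutralspine)
bfd = BFdistance / initialBFdistance
```

so `sb = 0` is a neutral back, `sb = 1` the calibrated maximal fault;
`bfd = 1` is the setup distance, `bfd = 0` the toes. Both feed the same
decreasing logistic audio-control mapping

```
y = 1 − 1 / (1 + exp(−α (x − β)))
```

with α = 10, β = 0.2 on the spine channel (output = degradation *quality*,
1 = pristine) and α = 15, β = 0.6 on the barbell channel (output = frontal
speaker gain; the surround gain is its complement). β leaves a margin of
clean execution before the feedback bites; α sets how abruptly it bites.

Around that core the package provides marker-table I/O with gap filling, an
offline WAV renderer of both feedback channels, repetition segmentation
from the vertical bar path (discard first 3 / last 2, average the middle
reps), the normality-branched statistical pipeline used to evaluate such
feedback (Shapiro–Wilk gate → paired/independent t or Wilcoxon; χ²
homogeneity; nested linear models for expertise compared by ANOVA;
Mann–Whitney and Kendall τ-b rating tests), and a synthetic capture
generator (22 body + 4 barbell markers at 100 Hz) with exact ground truth.

## Worked example

```r
library(sonolift)

# a 10-repetition session with a mid-lift spine fault peaking at sb = 0.4
# and the bar drifting to bfd = 0.2, 1 mm marker noise
ses <- simulate_session(simulation_config(n_reps = 10,
                                          spine_fault_amplitude = 0.4,
                                          barbell_drift = 0.2,
                                          marker_noise_sd = 1, seed = 7))
pr <- process_session(ses$trajectories, profile = ses$profile)
pr$summary
#>   participant_id condition n_reps_detected n_reps_retained  mean_sb  mean_bfd
#> 1           <NA>   control              10               5 0.199644 0.5922429
```

All ten repetitions are found; the discard rule keeps the middle five; the
retained-rep means recover the generator's targets (a raised-cosine fault
peaking at 0.4 averages 0.2 over a repetition; drift to 0.2 averages 0.6).
The audio controls for those frames:

```r
cs <- controls_from_derived(pr$derived)
round(cs[ses$reps$start_frame[5] + c(0, 150), ], 3)
#>      time quality gain_front gain_surround
#> 1201 12.0   0.908      0.002         0.998   # bottom: clean, immersive
#> 1351 13.5   0.076      0.998         0.002   # mid-lift fault: degraded, frontal
```

A cohort evaluation on simulated data (16 instruction vs 15 sonification
participants, effects at the defaults):

```r
coh <- simulate_cohort(seed = 3)
analyze_cohort(coh$records)
#> instruction.mean_sb : <paired_t> statistic = -4.313, p = 0.0006157, df = 15
#> sonification.mean_sb : <paired_t> statistic = -2.516, p = 0.0247, df = 14
#> delta_sb : <independent_t> statistic = -1.476, p = 0.1507, df = 29
#> <chi_square> statistic = 0.8595, p = 0.6507, df = 2   (expertise homogeneity)
#> ...
```

Both groups show a significant spine-bend reduction against control while
not differing from each other — the qualitative pattern such a study is
powered to see.

A command-line front end wraps the same functions
(`system.file("exec/sonolift", package = "sonolift")`): subcommands
`validate`, `convert`, `calibrate`, `derive`, `segment`, `summarize`,
`sonify`, `simulate`, `simulate-cohort`, `analyze`.

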