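---
title: "Models and methods behind sonolift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonolift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonolift)
```

`sonolift` is an offline re-implementation of the measurement and
evaluation chain of a music-based biofeedback system for the barbell
deadlift. This vignette documents the models, the parameters that matter,
the numerical choices, and — because the package ships its own synthetic
data generator in place of unavailable recordings — exactly what the test
conditions do and do not establish about real captures.

## The two monitored quantities

**Spine bend.** Four markers sit over the vertebrae L4, T12, T7 and C2.
The monitored quantity is the chain length `d0 + d1 + d2`, the sum of
consecutive Euclidean distances along the chain (mm). Forward flexion under
load stretches the posterior chain, so longer = worse; it is a scalar proxy
for the loss of midline stability, not a joint-angle model. It is invariant
under rigid motion of the body, which makes it robust to where the athlete
stands.

**Barbell–foot distance.** The bar should travel vertically over the
mid-foot. We project the two barbell extremity markers and the two
front-of-foot markers to the floor plane, take the perpendicular distance
from each foot marker to the infinite bar line, and keep the smaller of the
two. *Horizontal component* is thus read as perpendicular point-to-line
distance in the floor plane rather than a distance along the anteroposterior
axis: it is invariant to bar yaw and to which marker heights the vendor
export reports. The axis-projected variant is available via
`bf_distance(..., projection = "axis")` for comparison; the two agree
exactly when the bar has no yaw.

The distance is signed. The sign convention is anchored to a horizontal
axis estimated at calibration as the direction from the front-foot midpoint
toward L4 (`estimate_sign_axis()`), i.e. from the toes back toward the
athlete: the bar in its setup position over the mid-foot is on that side
(positive), and a bar drifting past the toe markers goes negative. The live
system needed signed values for exactly this distinction and a session's
own geometry defines the axis, so no extra configuration is required.

## Calibration and non-dimensionalisation

Three short static poses per athlete give the reference values: the
unloaded neutral chain length, the chain length at instructed maximal
(incorrect) bend, and the setup bar–foot distance. `calibrate()` takes the
**median over a 1.0 s window** (window and statistic are free choices: a
median over 100 frames resists marker jitter and brief occlusions; the
window must contain valid frames for the required markers in at least half
its frames, otherwise a calibration error names the offending pose).

With the profile `(neutralspine, maxspinebend, initialBFdistance)`:

$$sb = \frac{spinebend - neutralspine}{maxspinebend - neutralspine},
\qquad bfd = \frac{BFdistance}{initialBFdistance}.$$

Both are affine, order-preserving maps: `sb` is 0 at neutral and 1 at the
calibrated maximal fault (negative = extension); `bfd` is 1 at setup, 0 at
the toes, negative beyond them.

Frames with any required marker occluded produce `NA` in all derived
series and are excluded from every downstream mean; short interior gaps
can be bridged beforehand with `fill_gaps()` (linear interpolation, only
gaps up to a caller-chosen length, never at the capture edges).

## The logistic audio-control mapping

Both feedback channels use the decreasing logistic

$$y = 1 - \frac{1}{1 + e^{-\alpha (x - \beta)}}$$

- spine channel: $\alpha = 10$, $\beta = 0.2$, input `sb`, output the
  degradation *quality* in (0, 1) (1 = pristine);
- barbell channel: $\alpha = 15$, $\beta = 0.6$, input `bfd`, output the
  frontal gain, with the surround gain its complement (the gains sum to 1
  at every frame by construction).

$\beta$ is the midpoint ($y(\beta) = 0.5$) and acts as the tolerance
margin: at perfect form ($sb = 0$) the spine channel sits at
$1 - 1/(1+e^{2}) \approx 0.881$, **not** at 1. We deliberately do not clamp
this to 1 — the margin is part of the mapping's design (movement within the
margin should stay effectively undistorted), and whether 0.881 is audibly
neutral is a renderer concern. $\alpha$ sets the steepness of the
punishment onset.

## Offline rendering

The live degradation ran in a proprietary real-time patch; the offline
renderer defines the degradation deterministically as **sample-and-hold
decimation**: quality $q$ gives a hold length $\mathrm{round}(1/\max(q,
q_{\min}))$ samples ($q_{\min} = 0.01$ caps the worst case at a 100-sample
hold), applied piecewise within each control frame. $q = 1$ is exactly the
identity; $q = 0.5$ repeats every second sample. This reproduces the
aliased, "metallic" downsampling character in a reproducible way.

The spatial channel is rendered into two channels: output =
`gain_surround` × original image + `gain_front` × mid (mono) downmix in
both channels. Gains (0, 1) are the identity; (1, 0) collapses stereo
width to a frontal mono image. Channel naming is front/surround rather
than left/right — the live left/right assignment was an artifact of the
speaker patching, not of the method. Controls are zero-order-held between
10 ms control frames; no gain ramping is applied (the live smoothing, if
any, is undocumented; a ramp would only low-pass the gains).

Integer PCM samples are scaled by $2^{bits-1}$ on read and write, so a
read–process–write cycle with identity controls is bit-identical.

## Repetition segmentation

The bar height (midpoint of the two extremity markers) is low-pass
filtered with a zero-phase 2nd-order Butterworth at **4 Hz** (a deadlift
repetition lives well below 2 Hz; 4 Hz keeps the lift dynamics and removes
marker jitter; reflection padding tames the filter's edge transients).
Lift tops are local maxima with **topographic prominence ≥ 0.5 × the
signal range** and **≥ 1.0 s separation** (both exposed as arguments);
each repetition spans valley to valley around one peak, with the outermost
boundaries at the minima toward the signal ends. Spans tile the covered
range without overlapping frames. A flat signal yields zero repetitions,
by design not an error.

The first **3** and last **2** detected repetitions are discarded
(`retain_reps()`) to strip transient effects at the start and end of a
set; a 10-repetition session therefore keeps the middle 5. The session
quantity is the **two-stage mean** — the unweighted mean of the per-rep
means — which matches "a mean over repetitions" and is robust to
repetitions of different duration; a pooled-frame mean is available via
`summarize_session(..., method = "pooled")` since the original analysis
script is undescribed and either reading is defensible. Repetitions with
no valid frame for a quantity are excluded from that quantity's mean.

## The statistical pipeline

Every comparison passes through a Shapiro–Wilk gate at $\alpha = 0.05$ on
the quantity actually tested, and branches:

| design | normal | non-normal |
|---|---|---|
| within-participant (feedback vs control) | paired t | Wilcoxon signed-rank |
| between groups | pooled-variance Student t | Wilcoxon rank-sum |

Within-group comparisons are treated as **paired**: the same participants
perform the control and feedback sessions, and the gate is applied to the
paired differences. Between-group t tests pool variances (the era's
convention for balanced-ish groups; Welch is a flag away via
`var_equal = FALSE`). The branch taken is recorded on every result, so a
rerun on the same table reproduces the same decisions. Zero-variance
samples are routed to a degenerate result with a warning rather than a
crash. Group homogeneity uses Pearson's χ² without continuity correction.
All tests are two-sided; no multiple-testing correction is applied by
default (`adjust_holm()` is provided).

Movement improvements are per-participant deltas, feedback − control:
negative `delta_sb` and positive `delta_bfd` are improvements. The effect
of expertise is assessed by four nested OLS models of an improvement
(intercept-only; +feedback; +expertise; +both) compared to the null by
F tests. Expertise enters as an **unordered 3-level factor** even though
the levels are ordered, because the quantity of interest is a free
fitted mean per level (an ordinal polynomial contrast could not produce
three unconstrained level means); `ordered_expertise = TRUE` selects the
ordinal coding. Rating columns (7-point scales, 0 = no feedback
perceived) drop the zeros, then use Mann–Whitney U between groups and
Kendall's τ-b (tie-corrected) against improvements.

## The synthetic generator

No motion recordings are publicly deposited, so the package carries a
generator whose output is exact ground truth *under this package's own
kinematic definitions*:

- 22 body + 4 barbell markers at 100 Hz, matching the live capture model;
  the non-essential 16 body markers (head set, shoulders, elbows, wrists,
  6-marker trouser set) are kinematically plausible decoys so that
  readers, validators and role maps face realistic label sets — their
  motion is not physiological.
- Bar height follows one raised-cosine cycle per repetition; a repetition
  therefore has mean phase exactly 1/2, which makes session-mean targets
  analytic (a fault peaking at amplitude $a$ averages $a/2$).
- The spine chain is a zig-zag with T12/T7 offset posteriorly; the offset
  is solved per frame so the chain length hits the target `sb` exactly.
  The neutral pose carries a built-in 80 mm posterior bow so extension
  (negative `sb`, down to about −0.9) is representable.
- The bar drifts horizontally so `bfd` dips to the configured minimum at
  mid-lift.
- Marker noise is i.i.d. Gaussian per coordinate; a fixed seed gives
  bit-identical output.

Default session conditions mirror the study protocol: 10 repetitions at a
middle-low pace (3 s/rep), 100 Hz. Cohort defaults mirror the study
cohort: 16 instruction / 15 sonification participants, expertise mixes
2/9/5 and 3/6/6 (A/B/C), control-condition `sb` around 0.02 ± 0.25 and
`bfd` around 0.45, group improvements −0.108 / −0.124 (`sb`, sd 0.12) and
+0.573 / +0.755 (`bfd`, sd 0.73) — the magnitudes a study of this design
reports.

`simulate_cohort()` has two paths sharing one participant-effect model:
`method = "session"` synthesises full captures and pushes them through
derivation, segmentation and summarisation (the reference path), while
`method = "summary"` draws the summary means directly, which makes
hundreds of replicate cohorts affordable for calibration studies; a test
holds the two paths within 0.03 of each other on matched draws.

**What passing tests show — and what they do not.** The generator controls
`sb` and `bfd` directly; it contains no musculoskeletal dynamics, no soft
tissue artefact, no systematic marker misplacement, no fatigue drift, and
its occlusions are only those a test injects. Green tests therefore
establish that the *pipeline* is correct (geometry, segmentation,
normalisation, statistics, rendering), not that the *sensor model* matches
a given laboratory. On real captures the calibration statistics, the 4 Hz
cutoff and the prominence threshold are the knobs to re-examine first.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to exercise every code path with comfortable statistical
resolution: the segmentation sweep covers repetition counts 4–20, tempi
2–6 s and noise 0–3 mm (45 sessions); null calibrations use 500 replicates
per test (binomial SE ≈ 1% at the 5% level); power and coverage use 100
replicate cohorts of 15 + 15. Tolerances: closed-form logistic agreement at
1e-12; kinematic oracle agreement at 1e-9 (double-precision geometry);
clean-signal segmentation boundaries within 2 frames (20 ms); null
rejection rates within 5% ± 3%.

Degenerate inputs are contracts, not crashes: flat bar signals give zero
repetitions; discard rules that empty a session warn and return an empty
set (summaries then error, naming the session); constant samples are
branched as non-normal with a warning; coincident projected barbell
extremities raise a geometry error; a single expertise level raises a
singular-design error naming the term.

## Streaming contract (documented only)

The live topology streamed marker frames to a control process every 10 ms.
The offline package fixes the message contract without implementing a
transport: inbound `(timestamp, labelled marker positions)`; outbound
`(timestamp, quality, gain_front, gain_surround)`, computed by exactly the
functions documented here (`derive_series` row → `control_series` row);
the processing budget is one control frame. Any OSC/UDP binding that
honours this contract reproduces the offline numbers.

## Known limitations

- The chain-length proxy cannot separate thoracic from lumbar flexion and
  has no measured counterpart for cues like "shoulders back".
- The in-repo capture schemas (`tsv_wide`, `csv_long`) are documented
  stand-ins, not a vendor format; binary C3D is out of scope.
- The sample-and-hold degradation is a deterministic stand-in for the
  original patch's proprietary buffer manipulation; it reproduces the
  character, not the exact waveform.
- The statistics module reproduces the evaluation pipeline as specified
  (no correction for multiple tests by default); it is not a general
  inference framework, and mixed-effects re-analysis is out of scope.
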