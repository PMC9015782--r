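---
title: "Methods: post hoc quality control for markerless motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post hoc quality control for markerless motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapqc)
```

## The problem

Depth-camera ("markerless") motion capture of short structured motor tasks
is attractive for clinical movement analysis because it is cheap and fast,
but raw recordings are frequently compromised: clothing that absorbs
infrared light corrupts leg tracking, reflective floors add noise, subjects
drift out of the working volume, start with the wrong posture, or gesture
mid-task. Kinematic outcome parameters computed from such recordings can be
silently wrong — a subject who stands with open feet shows *less* postural
sway, which outlier screening at the parameter level would read as unusually
good balance. Quality control therefore has to happen at the raw-data level,
after acquisition (post hoc), and at a cost of seconds per recording.

`mocapqc` implements such a pipeline for seven task types: quiet stance
(POCO, and POCO_DUAL with a concurrent cognitive task), three short walks
toward the camera (comfortable speed SCSW, maximum speed SMSW, slow
narrow-base SLW), stepping in place (SIP) and repeated stand-up/sit-down
cycles (SAS). Recordings carry a 25-landmark skeleton stream (30 Hz) and/or
a 16-bit depth-image stream, for subjects 1.5–4.5 m from the camera.

## Motion profiles

A recording's depth stack is condensed into three images
(`compute_motion_profiles()`): the time-average of each pixel (frontal), the
per-frame average over the vertical image axis (top, rows = time) and over
the horizontal axis (side, rows = time). Averages are arithmetic means over
*valid* (nonzero) pixels only, so dropouts do not dilute the values; a
pixel with no valid contributor is 0, and a `valid_fraction` image records
coverage. A raw-sum variant is available (`aggregate = "sum"`), but the mean
is the default because its scale does not depend on recording length, which
makes profiles comparable across recordings. Orientation conventions (time
increasing downward; top columns = image x; side columns = image y) are
fixed and documented because raters must be able to compare figures across
recordings. For display, panels are contrast-stretched between the 1st and
99th percentile of nonzero values; raw arrays are never normalized.

## Characteristic signals

All signal definitions are this package's own landmark-based quantities —
deliberately the simplest definitions consistent with what QC figures need
to show. The landmark mapping is fixed: pelvis = SpineBase, hands =
HandLeft/HandRight, reference for arm motion = SpineShoulder.

* **Positions** — pelvis x/y/z over time. Samples with tracking confidence
  below 0.5 are interpolated linearly up to 0.5 s and left missing beyond
  that, so short dropouts do not fabricate motion and long ones stay
  visible.
* **Knee amplitude** (SIP) — knee height above its 10th-percentile
  baseline. The low quantile is a robust stance-height estimate because
  lifts occupy well under half the duty cycle.
* **Arm sway** — magnitude of the hand's displacement from its centered
  2 s rolling median, computed on hand position *relative to
  SpineShoulder*. The body-relative reference makes the signal exactly
  invariant to whole-body translation (walks, sidesteps, chair transfers);
  the rolling median additionally removes slow postural adjustment, so what
  remains are transient gestures.
* **Step events** (`detect_steps()`) — per-side lift signal (knee for SIP,
  ankle for walks) above its 10th-percentile baseline; a lift is a
  contiguous excursion above an amplitude gate (default 0.05 m), excursions
  closer than 0.25 s merge, and the contact is the drop to 20% of the lift
  peak. Gate-region counting was chosen over local-maxima detection because
  it is insensitive to sensor noise near flat peak tops, where maxima
  detectors either split or miss events.
* **Sit-to-stand phases** (`detect_sas_phases()`) — threshold-crossing
  segmentation of pelvis height between per-recording plateaus (lower/upper
  25% of the height range). Plateaus are estimated per recording so the
  segmentation is independent of subject stature and camera height. A
  transition still in progress at the end of the recording is returned
  marked incomplete.

## The quality taxonomy and automated detectors

Twelve criteria cover technical issues (signal disturbances, duration,
step-detection and phase-segmentation failures) and performance issues
(arms not down, backward/forward drift, open feet, task-unassociated
movements, sidesteps, support use), plus a free `OTHER`. Their
task-applicability is fixed (`criterion_table()`), and `run_autoflag()`
evaluates exactly the applicable detectors in taxonomy order.

Two thresholds are externally given: recordings of the 40 s tasks are
flagged when the duration deviates by **more than 1 s**, and stepping in
place is flagged when the subject moves forward (or backward) by **more
than 50 cm** — with a documented tolerant preset at 0.80 m, reflecting
field experience that drifts up to 80–100 cm may be acceptable. All
comparisons are strict (`>`): evidence exactly at the threshold never
raises, matching the "more than" wording. Every other threshold is an
explicitly heuristic package default, because the criteria are only
described qualitatively: feet width 0.15 m, movement excursion 0.10 m,
sidestep 0.15 m within a 1 s window (the rate limit distinguishes a step
from a slow lean), arms-at-start tolerance 0.05 m above hip height,
disturbance fraction 0.10, cadence bounds 0.3–3.5 steps/s, alternation
tolerance 20%.

Detector-specific choices:

* **DISTURBANCES** needs a notion of "where signal should be". The body
  silhouette is reprojected from the recording's own skeleton through the
  same documented pinhole/capsule body model the simulator uses (focal
  365.6 px at 512 px width, 24 capsules over the 25 landmarks); the static
  background (pixels valid in ≥ 60% of frames, e.g. the floor) forms a
  second region. The evidence is the mean over frames of the *worse* of
  the two regions' disturbed-pixel fractions — invalid pixels, or
  frame-to-frame changes above 200 mm (body flicker counts only while the
  pelvis is quasi-static, so locomotion does not register). Taking the max
  keeps a leg-tracking dropout from being diluted by a large clean floor
  and vice versa. On real data the capsule model will not fit perfectly
  and a small baseline fraction is expected; the 0.10 default leaves room
  for it.
* **BACKWARD** also covers "deliberate backward correction",
  operationalized as a ≥ 0.25 m backward excursion following a ≥ 0.25 m
  forward excursion — an interpretation, flagged as such in the
  documentation.
* **MOVEMENTS** on SAS excludes the detected transition windows (± 0.5 s)
  and the first 5 s, where arm repositioning is task-expected and judged
  by the ARMS criterion instead; on POCO_DUAL the flag carries a note that
  gesturing may accompany the concurrent cognitive task.
* **SUPPORT** and **OTHER** have no detector (support-object recognition
  is out of scope); they stay in the taxonomy for rating-sheet
  compatibility and are always returned unraised with note "manual-only".

## The synthetic-data generator

No clinical recordings can be shipped, so the simulator
(`simulate_recording()`) is a first-class module: it generates the study
conditions — 30 Hz skeleton streams, subject within 1.5–4.5 m,
512 × 424 depth frames (Kinect-v2 native; configurable) — with a purely
*kinematic* body model: a 25-landmark standing template scaled to stature,
sinusoidal leg lifts, linear walking translation, raised-cosine
sit-to-stand transitions, low-amplitude postural sway, 3 mm landmark noise
and 8 mm depth noise. A biomechanical model is unnecessary because every
detector operates on displacement and periodicity features. Task defaults
are the protocol's: 40 s for POCO/POCO_DUAL/SIP; SIP cadence 1.0 steps/s
(both legs counted, so 40 s yields 40 lifts); walks at 1.2 / 1.8 / 0.3 m/s
from 4.4 / 4.5 / 3.5 m; three SAS cycles in 18 s. The slow line walk's
kinematics are a stand-in (the protocol names the task but its exact
execution is not modeled); its detectors only use displacement and step
periodicity, which the stand-in does provide.

Depth frames are rendered from the skeleton by rasterizing capsules
between connected landmarks under a fixed pinhole model (implemented in
C++; the floor plane is rendered optionally). Twelve defect kinds can be
superimposed, each mapping 1:1 onto a criterion (`defect()`); ground truth
records everything injected, including true step times and phase bounds.
Two modelling notes: `extra_steps` is realized as same-side double-steps
(the left leg lifts where the right was due) because genuinely *inserted*
extra lifts at half-slot offsets merge with neighbouring lifts at any
plausible cadence and would be invisible to any detector; `missing_steps`
suppresses left-leg lifts starting from the second one, since suppressing
the very first lift sits at the sequence edge and breaks no alternation.
`clothing_noise` zeroes below-knee silhouette pixels (scaled so the stated
magnitude is the fraction of the whole silhouette lost) and adds
magnitude-scaled noise to lower-leg landmarks, reproducing the coupling
where poor clothing causes both disturbances and step-detection failures.
The only stochastic elements are the two noise sources, drawn from one
RNG stream seeded by `cfg$seed`, so simulations are bit-reproducible.

## Rating data model and concordance

Ratings are rows of (recording, rater, decision ∈ {keep, discard,
undecided}, multiselect criteria, comment, duration), persisted as CSV
with closed-vocabulary validation. For two raters,
`concordance_summary()` builds the per-task 3 × 3 confusion matrix —
unordered by default, because raters are interchangeable; an ordered mode
exists — and derives: concordance (trace/n), the unanimous keep / discard /
undecided rates (which sum to the concordance), strict disagreement
(keep-vs-discard only) and the undecided-involved discordance (the
remainder; in practice most discordance involves one undecided vote).
Percentages are exact fractions internally and only rounded for display.
Criterion frequencies are per rating (the denominator choice is documented
since per-recording or union-of-raters denominators are equally
defensible); selections are multiselect, so frequencies can sum above
100%. The pooled frequency equals the denominator-weighted mean of group
frequencies by construction.

## Validation strategy and problem sizes

Because detector correctness cannot be shown on real data here, the test
suite validates end to end against simulated ground truth:

* oracle tests — motion profiles against a brute-force per-pixel loop;
  step counts against a gate-region count; concordance rates against a
  pair-counting oracle;
* property tests — translation invariance, threshold monotonicity
  (raising a threshold never raises a flag), strictness at the boundary,
  applicability closure (no flag ever appears for a task outside its
  criterion's set), round-trip identity of the container, bit-level
  determinism under a fixed seed;
* a defect-recovery battery (`run_defect_battery()`): 50 seeds for every
  applicable (task, defect) pair at twice the detector threshold, plus
  20 clean seeds per task. The package passes with per-criterion precision
  and recall ≥ 0.9 and a clean false-positive rate ≤ 0.05. Step-detection
  flags on clothing-noise recordings are treated as the documented
  coupling, not false positives.

Battery simulations are skeleton-only except the noise defects and the
clean set, which render depth at 96 × 80 / 3 Hz — the disturbance
statistic is a resolution-independent pixel fraction, and this size keeps
the battery to a few minutes on one core. Unit tests use shorter
durations where the property under test allows it.

## What passing does and does not show

The simulator produces idealized kinematics: perfect task compliance up to
the injected defect, Gaussian noise, no soft-tissue or clothing physics, no
multi-subject scenes, no disease-specific movement patterns. Passing the
battery therefore demonstrates that the detectors recover *their own
criteria* reliably under the documented signal model — it does not
establish equivalence with human raters on clinical data, nor with the
proprietary kinematic algorithms of any commercial system (whose signal
definitions are not public; this package's signals are independent
reconstructions from figure-level descriptions). The headline human-rater
results of the motivating study (concordance around 70–92% per task,
median rating duration of a few seconds) depend on thousands of clinical
recordings and human judgment and are out of reach of a desk-scale
validation; the package's contribution is the instrumentation to produce
figures, flags and those statistics on new data.

## Known limitations

* Depth is rendered without occluders other than the optional support
  pole, and the silhouette reprojection assumes the default body
  dimensions; on real data the DISTURBANCES baseline will be nonzero.
* The correction heuristic for BACKWARD and all non-prescribed thresholds
  are heuristics to be tuned per site; they are configuration keys, not
  claims.
* SIP step counting counts each leg's lift as one step (both legs
  counted); sites that count strides should halve cadences.
* The container stores one recording per directory and is not intended as
  an archival format for multi-hour sessions.
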