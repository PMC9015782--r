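# mocapqc

Post hoc quality control for markerless (depth-camera) motion-capture
recordings of short structured motor tasks.

Clinical movement analysis with consumer depth cameras produces recordings
that are frequently compromised — infrared-absorbing clothing corrupts leg
tracking, reflective floors add noise, subjects drift out of the working
volume, start in the wrong posture, or gesture mid-task. Such problems can
silently bias kinematic outcomes (a subject standing with open feet shows
*less* postural sway, which parameter-level outlier screening reads as
unusually good balance), so screening has to happen on the raw data.
`mocapqc` is for clinicians and researchers running task-based motion
assessments who need to rate recording usability quickly and consistently.

The package covers seven task types — quiet stance (POCO, POCO_DUAL),
short walks toward the camera (SCSW, SMSW, SLW), stepping in place (SIP)
and stand-up/sit-down cycles (SAS) — and provides:

* a plain-text **recording container**: 25-landmark skeleton time series as
  CSV plus 16-bit grayscale PNG depth frames (value = millimeters, 0 =
  invalid);
* **motion profiles**: the depth stack condensed into three images —
  per-pixel time average *F*(y,x), and per-frame averages over the vertical
  and horizontal image axes, *T*(t,x) and *S*(t,y), each an arithmetic mean
  over valid (nonzero) pixels only;
* **characteristic signals** per task: pelvis position, per-side knee-lift
  amplitude (knee height minus its 10th-percentile baseline), body-relative
  arm sway (hand displacement from its rolling 2 s median), step detection
  from per-side leg lifts, sit-to-stand phase segmentation of pelvis height,
  and stance width;
* **automated flags** for a 12-criterion quality taxonomy. Each detector
  compares an evidence value against a threshold, strictly: the duration
  criterion raises when |duration − 40 s| > 1 s, the drift criteria when the
  pelvis moves forward/backward by more than 0.50 m (a tolerant 0.80 m
  preset exists); the remaining thresholds are documented heuristics;
* a **two-rater rating data model** (keep / discard / undecided plus
  multiselect criteria) with per-task 3×3 confusion matrices, concordance =
  trace/n, unanimous keep/discard rates, strict (keep-vs-discard)
  disagreement, criterion selection frequencies and the median rating
  duration;
* a **synthetic recording simulator** with twelve injectable,
  ground-truth-labeled defect kinds, so the whole pipeline is testable
  without clinical data.

## Worked example

Simulate a 40 s stepping-in-place recording whose subject drifts 0.8 m
toward the camera, then flag it:

```r
library(mocapqc)

sim <- simulate_recording(simulation_config("SIP", seed = 7),
                          list(defect("forward_drift", 0.8)))
run_autoflag(sim$recording)
#> DURATION       ok      evidence=0 s threshold=1
#> STEP_DETECTION ok      evidence=0 plausibility threshold=0.2
#> BACKWARD       ok      evidence=0.001933 m threshold=0.5
#> FORWARD        RAISED  evidence=0.8109 m threshold=0.5
#> MOVEMENTS      ok      evidence=0.01955 m threshold=0.1
#> SUPPORT        ok      evidence=NA  threshold=NA  (manual-only)
#> OTHER          ok      evidence=NA  threshold=NA  (manual-only)

nrow(detect_steps(sim$recording))
#> [1] 40
```

Only the criteria applicable to SIP are evaluated, in fixed taxonomy
order. The forward criterion is raised because the maximum anterior pelvis
displacement (0.81 m) strictly exceeds the 0.50 m threshold; stepping
itself is intact (40 alternating contacts, matching the 1.0 steps/s
cadence over 40 s), so step detection stays quiet. With the tolerant
preset, `run_autoflag(sim$recording, flag_config(preset =
"tolerant_forward"))` leaves FORWARD unraised.

From a shell, the same pipeline runs over directories of recordings:

```sh
inst/cli/mocapqc simulate --out recs --tasks SIP,POCO --n 2 --seed 1
inst/cli/mocapqc figures  --in recs --out figs     # PNGs + rating template
inst/cli/mocapqc autoflag --in recs --out flags    # flags.csv / flags.json
inst/cli/mocapqc stats --ratings ratings.csv --out stats
```

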