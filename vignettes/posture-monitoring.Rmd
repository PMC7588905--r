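---
title: "Bounding-box postural-change monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding-box postural-change monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturewatch)
```

## The monitoring model

posturewatch quantifies the physical activity of a person observed by a
fixed camera whose pose-estimation front end reports 17 named body
keypoints once per second. Instead of analysing the keypoints themselves,
everything is reduced to the **pose bounding box** — the axis-aligned
rectangle spanned by the min/max x and y of the keypoints. Between two
boxes (consecutive seconds of a stream, or a prediction and a reference
for the same image) three change metrics are computed:

* **ΔHeight** = |height(curr) − height(prev)| — posture transitions such
  as standing up or sitting down change the box height;
* **ΔWidth** = |width(curr) − width(prev)| — in-place limb and hand
  activity widens and narrows the box;
* **ΔDistance** = Euclidean displacement of the box center — locomotion
  moves the whole box.

The three channels map onto the three monitored parameters — *pose
conversion*, *body movement* and *positional change* — in that order.
The mapping is a configurable bijection (`default_channel_map()`):
nothing in the geometry forces it, but each channel is the dominant
signature of its parameter, and the dominant-channel classifier
(`label_dominant()`) makes the association operational. Ties are broken
by the fixed priority positional change > body movement > pose
conversion, on the reasoning that a displacement large enough to tie a
shape change is more likely real locomotion; an all-zero record gets a
`"none"` sentinel rather than a fabricated class.

All deltas are absolute magnitudes. Signed versions would distinguish
standing up from sitting down, but the downstream summaries are
per-minute averages and daily totals of activity *amount*, for which
direction is irrelevant and sign cancellation would be actively harmful.
The center is used as the distance anchor because it is the only choice
invariant under pure translation of the box.

## Filtering

Frames are admitted by a `filter_policy()`:

| parameter         | default | meaning |
|-------------------|---------|---------|
| `score_threshold` | 0.5     | overall pose confidence below this drops the frame (the conventional pose-estimation cutoff) |
| `multi_person`    | `"keep"`| `"keep"` retains frames with a second person (care-visit variation stays visible); `"exclude"` drops them so only unattended activity is recorded |
| `max_gap`         | 2 s     | maximum timestamp gap across which a delta is still formed |
| `min_kp_score`    | 0       | per-keypoint cutoff when deriving the box; 0 means all reported keypoints are used |

`max_gap` exists because absent-person seconds are never stored: pairing
frames across a long absence would attribute the whole displacement of a
room exit and re-entry to a single second. Two seconds is the smallest
value that still bridges a single dropped frame (one low-confidence
second), which is the common transient failure of the estimator.

## Aggregation

The per-minute evaluating data is a simple moving average of window
60 s. The default is the *tumbling* form: records are grouped into
`[t, t+60)` windows aligned to the wall-clock minute grid, giving one
value per minute as plotted on clock-time axes. A trailing *sliding*
variant (`align = "sliding"`) is available but not the default, since
one value per minute is what the day-level charts consume. Empty minutes
are **omitted, not zero-filled**: a zero would conflate "present but
still" with "not observed", which are different care-relevant states.

Daily summaries sum the raw per-second deltas per civil day and report
`active_hours = valid frames / 3600` — total observed activity time.
Day boundaries use the civil day of the epoch-second timestamps
directly; no timezone arithmetic is applied beyond that. Daily totals
are sums of per-second deltas rather than sums of per-minute means; the
two differ only through partially-filled minutes, and the per-second sum
is the quantity with a conservation law (see below).

`presence_intervals()` segments valid frames into maximal runs separated
by gaps longer than `min_gap` (default 300 s — shorter interruptions are
estimator dropouts rather than genuine absences). Waking time, lunch
breaks and sleep are read off these intervals.

## The agreement protocol

To evaluate an estimator against ground truth, the same three formulas
are applied *across sources*: for each image, the predicted box and the
reference box produce a difference triple K = (k_height, k_width,
k_distance). `bin_report()` assigns each K to one of three ranges —
K ≤ 10, 10 < K ≤ 30, K > 30 pixels, upper edges closed — and reports the
percentage of images per range and channel. The comparison is per-image
by `image_id`; an id present in only one file is an error, because
silently dropping it would bias the percentages. A `"sequential"` mode
that compares within-source consecutive-pair metrics instead is kept
behind a flag for completeness, but the per-image pairing is the
meaningful protocol for an unordered evaluation dataset.

## The simulator

`simulate_stream()` generates the package's own test bed: a stylized
articulated 17-keypoint figure in a 320 × 240 px scene (a ~4 m × 3 m
room, so roughly 80 px/m), one frame per second, driven by a schedule of
activity segments. What it emulates, and the defaults chosen:

* **Standing/walking figure** 150 px tall × 50 px wide (a person
  prominent in frame at this resolution); **sitting** is 60 % of
  standing height at identical width, so a stand↔sit conversion is a
  pure ΔHeight event; **lying** is 150 px wide × ~25 px tall.
* **Walking** translates a rigid standing figure at `speed` px/s
  (default 8 px/s ≈ 0.1 m/s — the slow indoor shuffling of a person
  recovering from leg injury), ping-ponging off wall margins so the
  figure never leaves the frame.
* **Hand activity** oscillates the wrist offsets (amplitude 12 px,
  period 2 s) and the elbows at half amplitude, symmetrically, so box
  width alternates by twice the amplitude while height and center stay
  fixed.
* **Transitions** between adjacent segments are linearly interpolated
  over `ramp` seconds (default 3 s) so conversion spikes are finite and
  testable; an appearance after absence is instantaneous.
* **Noise** is i.i.d. Gaussian per coordinate per second (`noise_sd`
  pixels), added after placement and clipped to the frame. 2 px is used
  as the "realistic jitter" condition in the self-tests.
* **Confidence scores** (overall and per keypoint) are drawn from
  Beta(mean·κ, (1−mean)·κ) with mean 0.85, κ = 40 — mostly confident
  detections that occasionally dip, exercising the 0.5 threshold path.
  κ = Inf is the degenerate constant-score limit, used where a property
  under test (for example the active-hours counting identity) should
  not depend on confidence sampling.
* **Visitors** set `persons = 2` while keeping the subject's keypoints
  as the single reported pose — exactly what a single-person estimator
  does when a caregiver enters — so the `multi_person` policy can be
  exercised end to end.
* **Absence** emits no frames at all, matching a pipeline in which an
  empty detection is never stored.

What the simulator deliberately does **not** model: gait articulation
(the walking figure is rigid), perspective scaling with distance from
the camera, occlusion, estimator keypoint-swap failures, or lighting
effects beyond the confidence model. Passing tests therefore demonstrate
that the *algorithms* are correct under known kinematics and noise; they
do not certify performance of any particular pose estimator on real
footage — that is what the agreement protocol is for.

### Ground truth and "unambiguous" minutes

Each simulation returns per-second labels (activity, segment, persons,
emitted, transition). `expected_minute_labels()` derives from them the
minutes whose dominant channel is defined a priori: every second of the
minute, plus the second before it (which pairs into the minute's first
delta), emitted from one segment whose activity drives a single channel
deterministically — walking drives positional change, hand activity
drives body movement — with no interpolation-ramp second involved.
Static activities produce an all-zero signal at zero noise (their true
label is "none", indistinguishable from noise at any positive jitter),
and transition or visitor minutes are mixtures; such minutes are
excluded from recovery scoring rather than assigned a guess. Stand↔sit
ramps are instead checked at the per-second level, where their expected
label (pose conversion) is well defined.

## Numerical choices

* **Serialization** writes doubles with 17 significant digits, the
  smallest count guaranteeing bit-exact double round-trips; the NDJSON
  reader rejects malformed lines with their line number, and
  out-of-order or duplicated timestamps are errors, never silently
  sorted. Sub-second timestamps are rejected rather than rounded — the
  pipeline is defined on a 1 s grid.
* **Conservation**: per channel, the sum of minute means × counts and
  the sum of daily totals both equal the raw per-second sum to 1e−9
  relative tolerance (exactly, in practice, since the same additions are
  regrouped).
* **Scale covariance**: the simulator's `coord_scale` multiplies all
  geometry *after* drawing standard-normal jitter, so one seed yields a
  bit-exactly scaled scene; doubling coordinates doubles every delta,
  mean and total exactly (multiplication by 2 is exact in IEEE 754).
  This is the pixel-unit covariance any consumer can rely on when
  changing camera resolution.
* **Bin boundaries** are closed on the upper edge (K ≤ 10, 10 < K ≤ 30),
  and a value exactly on an edge goes to the lower range.

## Problem sizes

The self-tests and the acceptance script use a 2 h schedule (7 200
frames) for recovery and conservation checks, two scheduled days (5 400
emitted frames) for the active-hours identity, and one full 24 h day
(86 400 frames) for the end-to-end run — sizes at which every property
of interest is already exercised while the whole suite stays fast on a
single CPU.

## Known limitations

* A single subject per scene: multi-person scenes are handled only as
  the keep/exclude policy, not by tracking identities.
* The channel→parameter mapping is heuristic; a crouching walk or a
  seated arm swing can load an unexpected channel. The mapping is
  configurable, and minute-level classification should be read as a
  summary, not a clinical measurement.
* 2D only: movement toward the camera appears as a height/width change,
  not a positional one.
* Civil-day boundaries assume the timestamps already carry local clock
  time.
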