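---
title: "Counting caged hens from detection streams: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting caged hens from detection streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagecount)
```

## The problem and the model

An inspection robot traverses a row of layer cages at constant speed with a
side-facing camera. An upstream object detector emits, per frame, bounding
boxes for two classes: *chicken heads* (heads remain visible when densely
packed bodies occlude each other, making them the reliable proxy for a live
bird) and *fences* (the vertical railings delimiting cages). `cagecount`
implements everything downstream of the detector: cage segmentation, head
filtering, and per-cage counting.

The counting rule is a three-phase state machine over the per-frame fence
count `f` and the horizontal box coordinates only — vertical extent carries
no information about cage membership in this geometry:

* **`f = 2` (COUNTING).** The fence pair defines the cage's lateral span.
  Heads inside the span are counted and the cage's running maximum is
  updated, together with the earliest frame attaining it (the *key frame*).
  Any transition streak in progress is cancelled: a brief drop in fence
  count is interpreted as a detector false negative, not a cage boundary.
* **`f ≤ 1` (TRANSITION).** Once counting has begun, consecutive sub-two
  fence frames accumulate a streak. When the streak reaches
  `transition_frames` (N) the cage is deemed passed and its record —
  ordinal id, maximum count, key frame, key-frame timestamp — is emitted.
* **`f ≥ 3`.** The frame is ignored entirely (neither counting nor streak
  bookkeeping): at the intended standoff a third railing is never fully in
  view, so such frames carry no trustworthy cage assignment.

The maximum over a cage's frames, rather than any single frame's count, is
the load-bearing idea: a bird occluded at one instant is usually visible at
another, so the running maximum converges to the true occupancy as the
number of distinct viewing geometries grows.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `transition_frames` (N) | 10 | frames | sub-two-fence streak that ends a cage; at 30 fps and 0.2 m/s this is 1/3 s ≈ 6.7 cm of travel |
| `confidence_min` | 0.25 | — | score floor applied before any logic; detectors emit many low-score boxes and the machine should not key on them |
| `span_mode` | `"outer"` | — | `outer` = envelope of both fence boxes; `inner` = between the facing fence edges |
| `membership` | `"center"` | — | head is in-span if its x-center is inside (closed interval); `full_box` requires whole-box containment |
| `zero_fence_in_streak` | `TRUE` | — | zero-fence frames feed the transition streak once counting has begun |

Where the procedure is under-determined, the package makes these choices:

* **`outer` as default span.** "Minimum and maximum horizontal coordinates
  of the fence boxes" admits either reading; the outer envelope is the more
  permissive one and matches the visual convention of excluding only heads
  beyond the railings. Both modes are implemented and the worked-example
  fixture is built clear of the railings so that both agree on it; neither
  is asserted to be *the* canonical behaviour.
* **Center-x membership.** Robust to heads straddling a railing, where
  whole-box containment would flicker with box jitter. The boundary is
  closed: a center exactly on the span edge counts.
* **Emission when the streak *reaches* N.** "Fewer than ten" is a false
  detection and "exceed ten" ends the cage; the boundary case is resolved
  as emission exactly at N. With N = 10 a 9-frame dropout is forgiven and a
  10-frame one ends the cage.
* **Zero-fence frames feed the streak.** Only the drop to one fence is
  canonical, but mid-transition frames with no fence at all would otherwise
  stall the machine between cages; the flag restores strict
  one-fence-only semantics if wanted.
* **Detection time = key-frame timestamp**, not emission time: the record
  stores the frame that exhibits the reported count, which is also the
  image worth keeping.
* **Key-frame ties break to the earliest frame** — deterministic and
  reproducible; this falls out of using a strict `>` when updating the
  running maximum.
* **End-of-stream flush.** A pending cage with a positive running maximum
  is emitted when the stream ends (the robot stops at the row end; the last
  cage would otherwise be lost). A mid-stream emission at streak N is
  *not* gated on a positive maximum, so a pathological segment between two
  fence pairs with no heads can legitimately produce a zero-count record;
  the flush is gated, because an empty tail after the last emission is not
  a cage.
* **Degenerate inner spans** (overlapping fence boxes under
  `span_mode = "inner"`): `cage_span()` raises a contract error when called
  directly, but inside `count_stream()` such a frame is treated like
  `f ≥ 3` — ignored — so one malformed frame cannot abort a whole pass.

## What the simulator emulates

`simulate_inspection()` builds a 1-D world: cages at fixed pitch, each
`[fence | interior | fence]`, with static head positions inside the
interior; the camera advances `robot_speed_mps / fps · px_per_m` pixels per
frame and projection is pure translation. Defaults mirror the acquisition
setup the package targets: 1280×720 frames at 30 fps, 0.2 m/s robot speed,
~50 cm standoff (`px_per_m = 1200`, so a 0.6 m cage interior spans 720 px),
cages of 0.6 m holding 5–8 birds, 5 cm railings. A cage interior therefore
takes `0.6 / 0.2 × 30 = 90` frames to traverse. Boxes partially outside the
frame are clamped; a box fully outside is absent from that frame.

**Cage spacing.** `gap_between_cages_m` defaults to 1.1 m — at least one
view width (1280 px / 1200 px·m⁻¹ ≈ 1.07 m). This is the geometric
realization, under pure translation, of the acquisition protocol's guarantee
that the field of view covers two railings *without including a third*: with
contiguous cage modules and translational projection, some pair of railings
(possibly from two different cages) would be visible in every frame, the
fence count would never fall below two, and no exit rule keyed on fence
count could ever fire. In the real system the guarantee is produced by
standoff, perspective and oblique-angle invisibility of neighbouring
railings; the simulator produces it by spacing, which yields the same
observable — per-cage episodes of exactly two fences separated by
single-fence (briefly zero-fence) transitions — with exact ground truth.
Narrower gaps trigger a warning and are allowed, for studying exactly this
failure mode.

**Noise model** (`apply_noise()`): per-head per-frame Bernoulli misses,
Poisson false-positive heads at uniform positions, Gaussian box jitter,
fence-dropout bursts that remove one railing (a random side per burst) for
a sampled number of consecutive frames, and Gaussian confidence scores
clipped to [0, 1]. These are the simplest distributions exhibiting the
failure modes the counter must survive; all parameters live in
`noise_config()`. Geometry and noise take separate seeds so one layout can
be re-noised.

**What it does not emulate — and what passing tests therefore do not
show.** Misses are independent across frames, but real occlusion is
*persistent*: a bird tucked behind others can stay hidden for the entire
pass. Under i.i.d. misses the probability that a head evades all ~70
counting frames is negligible, so the multi-frame maximum recovers full
occupancy at miss rates where a real system undercounts; conversely,
false-positive heads landing in-span can push the maximum *above* the true
occupancy (recognition rates above 100% in the demo are this effect, which
a single snapshot largely avoids). The simulator also renders no pixels, no
lighting, no perspective, no bird motion, and no vertical cage layers.
Passing the recovery suites therefore validates the *state machine and
filtering logic*, not detector accuracy on farm footage. The demo's
comparison of single-frame-at-center counting against the multi-frame
maximum on identical noisy streams preserves the *direction* of the
multi-frame advantage; its magnitudes are artifacts of the noise model.

## Evaluation conventions

* **Matching** is greedy in descending confidence, one-to-one, each
  prediction claiming the highest-IoU unmatched truth at or above the
  threshold — standard detection practice. Tests bound its match count
  against an exhaustive optimal assignment on small instances.
* **AP** uses the 101-point interpolated precision–recall curve, the
  convention the AP50:95 name implies; `ap_50_95()` averages thresholds
  0.50 to 0.95 in steps of 0.05. Tests check equality (to 1e-4) against an
  independent re-implementation that computes each recall point by direct
  scan, and invariance under monotone confidence rescaling.
* **Counting rates** — sample selection (samples kept by thresholding /
  complete-cage samples), chicken selection (heads kept / heads detected)
  and chicken recognition (heads detected / actual birds) — are returned as
  fractions; `as_percent()` rounds half-up to one decimal, matching how
  such tables are printed (base R's banker's rounding would differ on
  ties). Zero denominators return 0 flagged `undefined` rather than
  erroring, so batch evaluation never aborts.

## Reference network blocks

The two architectural ingredients of the upstream detector are provided as
plain-array, training-free forward passes with strong structural
invariants, at desk scale:

* **Coordinate attention**: mean-pool over width and height separately,
  concatenate the directional descriptors, shared 1×1 transform (reduction
  ratio 32, the common default) with ReLU, split, per-direction 1×1
  transforms with logistic squashing; the output is the input modulated by
  `a_h[c, i] · a_w[c, j]`. Factors are strictly inside (0, 1) for finite
  inputs, so output magnitude never exceeds input magnitude element-wise.
* **Reversible blocks**: additive coupling `(x1, x2) → (x2, x1 + F(x2))`
  with `F` a 1×1 linear map plus tanh (its internals are not prescribed at
  this granularity; any pointwise parametric map preserves exact
  invertibility). Columns connect levels additively — the lowest level
  passes through a reversible block, level *l* adds a coupling of the new
  level *l − 1* — so a whole column pass inverts level-wise and any number
  of stacked columns can be unwound exactly. Reconstruction error is
  checked below 1e-5 across random shapes and depths; in double precision
  it is ~1e-15, so the bound is loose by design.

## Problem sizes and determinism

The test suite runs entirely on synthetic data built at test time: 50
noiseless recovery runs of 3–20 cages, 1,000 random fence-count sequences
against a brute-force run-length oracle, 100 random reversible instances,
and 5 random 20-box AP sets — sizes chosen so the full suite completes in
about two minutes on one core while keeping the binomial/assignment checks
statistically meaningful. Every stochastic test fixes its seed; simulation
is bit-identical given a seed, and all CLI commands are idempotent on
identical inputs and seeds, with a config hash carried in stream metadata
and reports for provenance.

## Known limitations

* The N-frame rule cannot distinguish a long fence dropout from a real
  transition: two back-to-back sub-N dropout bursts merge into a run ≥ N
  and split a cage, and a 9-frame gap between two real cages merges them —
  both are inherent to the rule, are exercised deliberately in the tests,
  and match a brute-force interpretation of the fence-count sequence.
* Multi-cage views (`f ≥ 3`) are ignored, not disambiguated; handling rows
  where a third railing is chronically visible would need a different
  segmentation signal.
* Cage localization is by timestamp only; mapping records to physical cage
  coordinates is out of scope.
* The simulator's i.i.d. miss model overstates multi-frame robustness, as
  discussed above.
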