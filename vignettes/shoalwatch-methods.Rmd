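---
title: "Methods: video-based behavioural welfare indicators for tank-reared fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based behavioural welfare indicators for tank-reared fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Group-housed juvenile salmonids express their welfare state partly through
group-level behaviour: how tightly the school packs together (cohesion), how
much the fish move (activity), how much time they spend under structural
enrichment, and how quickly they resume normal swimming after a frightening
novel stimulus (neophobia). `shoalwatch` quantifies these four indicators
from fixed overhead video of circular rearing tanks, together with a
synthetic tank-video simulator that provides ground truth for validating
every stage of the measurement chain.

The pipeline is: per-pixel statistical background model of the static scene
→ foreground segmentation by background subtraction → connected-component
object detection → main-group assignment and frame-to-frame linking →
per-clip behavioural metrics → multi-week aggregation.

## Background model and segmentation

The tank scene (floor, wall shadow, enrichment structure) is static over a
clip: lighting is constant and the camera fixed. Each pixel's background is
therefore summarised by its temporal **lower median** over a subsample of
frames, with a scaled MAD (`1.4826 * MAD`, again lower-median) as spread.
The median tolerates fish transiting a pixel in up to half of the sampled
frames; the lower-median tie rule makes the estimate deterministic.

A pixel is foreground when its deviation from the background location (in
the direction given by the polarity, default dark fish on a light floor)
exceeds `k_sigma` (default 4) times `max(spread, min_spread_floor)`
(floor default 1 intensity unit, so noise-free synthetic scenes keep a
finite threshold). Two numerical details matter:

* **Spread capping.** Pixels that the school occupies in a sizeable share
  of sampled frames have a MAD inflated by the fish themselves; without
  intervention their threshold rises until the fish are missed. The spread
  is therefore capped at `spread_cap_factor` (default 3) times the median
  spread of the monitored region — a robust proxy for the true sensor
  noise.
* **Opening.** The raw mask is cleaned by morphological opening with a disc
  of radius `r_open` = 1 px, removing salt noise at the cost of eroding
  objects thinner than about 3 px. Fish must therefore be resolved at
  roughly 2 px per body *width* or better; the renderer refuses scenes
  below 2 px per body length outright.

A limitation inherited by any median background model: a school that parks
tightly on the same spot for more than half of a clip becomes part of the
background and is partially lost. The model assumes fish keep moving, which
holds in flowing rearing tanks.

## Detection, size model and tracking

Foreground masks are labelled with 8-connected components (4-connectivity
available); components under `min_blob_px` (default 3 px) are discarded.
Centroids are **intensity-weighted** by the background-subtraction deviation
image, which recovers sub-pixel positions far more stably than binary-mask
means (binary centroids jitter by ~0.25 px frame-to-frame, enough to bias
displacement metrics upward by several percent at cruising speeds).

The single-fish area is estimated as the binned mode of the areas of
isolated-fish candidates (objects below the median object area); when fish
are essentially never isolated the estimator falls back to total detected
area divided by the nominal count. Body length derives from the area and an
assumed 4:1 length-to-width ratio. A reference session's single-fish area
yields a growth-correction factor (`reference / current`, clamped to (0,1])
so that area-based metrics remain comparable as fish grow; all distance
thresholds scale with the current body length for the same reason.

Objects are clustered per frame by single linkage with cutoff 1.5 body
lengths; the cluster with the largest summed estimated fish count is the
main group; members farther than 2.5 times the RMS member radius from the
group centroid are re-labelled outliers (one pass); everything else is an
individual.

Frame-to-frame correspondence uses greedy mutual-nearest matching with two
gates: a distance gate of 2 body lengths per frame step, and a **size gate**
rejecting matches whose areas differ by more than a factor 1.5. The size
gate matters: when two fish merge into one blob (or a blob splits), matching
a single fish to the merged object injects a centroid jump of up to half the
separation; such identity-violating matches inflated measured activity by
7–12% before the gate and are simply dropped (unmatched objects contribute
no displacement). Objects touching the boundary of the camera's field of
view are flagged and excluded from linking for the same reason — their
centroid moves as the visible part changes.

## The behavioural indicators

**Group cohesion** is the ratio of the area occupied by the main group to
the monitored tank area, averaged over frames and multiplied by the growth
correction factor. "Occupied area" is realised as the convex hull of the
main-group member centroids dilated by one body radius (exact Minkowski
area `A + P*r + pi*r^2`); a single merged blob contributes its own pixel
area, so the measure degrades gracefully from many small objects to one
big one. A blob-area variant is available behind `cohesion_mode = "blob"`.
The mean ratio is scored categorically: **0 (tight)** below 0.25,
**2 (dispersed)** above 0.75, **1 (loose)** in between, with both
boundaries assigned to "loose" — the printed rule gives strict
inequalities for tight and dispersed, so the boundaries can only belong to
the middle class.

**Activity** is the estimated-fish-count-weighted mean of match
displacements, pooled over all frame pairs, reported in cm per frame step
and cm/s. Weighting by fish count makes a 10-fish blob moving 1 cm count
ten times a singleton moving 1 cm. A z-score helper
(`standardise_activity()`) is provided for cross-clip analysis scaling but
is not baked into the metric.

**Enrichment occupation** is 100 × (fish pixel area inside the enrichment
footprint) / (total fish pixel area), averaged over frames with any fish.
The enrichment structure is static, so it lives in the *background* model;
its footprint is recovered either from a configured disc/polygon or
automatically as the largest dark connected component of the background
location raster under an Otsu threshold. Otsu was chosen over a
median-minus-k-MAD rule after the latter proved unstable when the footprint
covers a large share of the view (the MAD then includes the footprint
itself); a minimum between-class contrast of 20 intensity units guards
against splitting an enrichment-free unimodal background.

**Latency to resume normal swimming** (novel-object trials): an object
emits a dart event when its speed exceeds 3 body lengths/s for at least 2
consecutive frame steps; event time is the excursion onset. Windows of 10 s
slide in 1 s steps from the trial start; normal swimming resumes at the
first window containing darts from fewer than 2 fish (distinct objects,
counting a merged object by its rounded fish-equivalents). If no window
qualifies the trial is right-censored at the clip duration and flagged; the
square-root export transforms only uncensored latencies. Window placement
is sliding by default because 1 s resolution costs nothing; a tiled scan
(`window_step_s = 10`) reproduces coarser manual scoring. The module also
accepts externally scored event tables (`time_s`, `subject_id`) so the same
rule can be applied to human annotations.

## The simulator and what it does (not) emulate

`simulate_school()` is a discrete-time correlated random walk in a 1 m
circular tank: each agent's new heading is the direction of a weighted sum
of its previous heading (weight 0.6), the unit vector to the group centroid
(weight `1/(1 + dispersion)`), and — for agents outside the enrichment
disc — the unit vector to the enrichment centre (weight
`2.5 * enrichment_affinity`), plus Gaussian angular noise (sd 0.4 rad per
step at the default 10 fps). Agents move at exactly
`mean_speed_cmps / fps` per frame and reflect specularly off the wall, so
the ground-truth mean step length equals the nominal speed by construction.
Swimming polarity is deliberately not modelled: the cohesion construct
needs controllable dispersion, not alignment, so a full zone-based
interaction model would add parameters without adding testable behaviour.

Defaults mirror the study system they emulate: a 100 cm tank of which the
camera monitors the lower half, a 70 cm circular enrichment footprint,
body length 5 cm and cruising speed 5 cm/s (about one body length per
second, typical for salmon parr), 10 fps (fast enough to resolve darts,
cheap enough for desk-scale tests), 8-bit frames with fish at intensity 40
on a ~200 textured floor and additive Gaussian noise (sd 2 by default).
Fish are rendered as 4:1 ellipses oriented along the velocity with 3×3
supersampled edge coverage — hard-edged rasterisation was found to alias
centroid positions badly enough to corrupt displacement recovery, and real
optics blur edges anyway.

Novel-object stimulation draws per-fish darts from an inhomogeneous Poisson
process with rate `r0 * exp(-(t - onset)/tau)`; a dart multiplies speed by
6 for 0.5 s. The recovery tests use `r0 = 0.4` darts/fish/s and
`tau = 10` s, which puts the resumption time comfortably inside a 60 s
clip at 20 fish.

The simulator does **not** emulate: occlusion by the enrichment plants
(the structure darkens the scene but never hides fish), hydrodynamics,
schooling polarity, individual size variation, growth within a clip, water
surface glare, or compression artefacts. Passing the recovery tests
therefore demonstrates that the measurement chain is correct under
idealised imaging, not that it is robust to every nuisance of a real rig.

## Problem sizes used by the validation suite

The parameter-recovery suite runs 20 fish in 256×256 px clips of 60 s at
10 fps. Dispersion-to-cohesion monotonicity uses dispersion levels
(0.5, 2, 4, 8, 16) × 10 seeds; activity and occupation recovery use 10
well-separated schools (dispersion 256); latency recovery uses 20 seeded
novel-object clips; determinism uses a 2-tank × 2-week × 2-timepoint
mini-study at 160×160 px. The dispersion ceiling of 16 for the cohesion
sweep is deliberate: at 20 fish in a 1 m tank, nearest-neighbour spacing
exceeds the 1.5-body-length linkage cutoff somewhere above dispersion ~16
and the "main group" construct itself dissolves — at the study's real
densities (hundreds of fish per tank) the construct remains connected at
far higher spreads.

Latency ground truth is compared against dart events of agents *visible to
the camera* at dart onset; the camera cannot count fish it cannot see, and
the measured and true rules are applied to the same observable population.

## Known limitations

* A tightly packed, stationary school can bleed into the background model
  (median contamination above 50% occupancy) and be undersegmented — in the
  extreme, a clip yields no detections at all and its metrics are flagged
  missing rather than reported; aggregation excludes such clips explicitly.
* Occupation compares pixel areas, so fish straddling the footprint edge
  contribute fractionally; at very low resolutions this differs from a
  per-fish count by a few points.
* No persistent identities: tracklets are frame-to-frame chains, so darts
  by the same fish separated by a tracking break count as separate
  objects. The latency rule counts distinct objects per window, which is
  conservative.
* The growth-correction factor is a ratio of estimated single-fish areas;
  it corrects area-based metrics multiplicatively and is no substitute for
  a calibrated length measurement.
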