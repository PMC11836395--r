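# shoalwatch

Video-based behavioural welfare indicators for tank-reared fish.

## What it does

Fixed overhead cameras over circular rearing tanks produce footage in which
a school of juvenile fish appears as dark moving blobs on a static, brighter
tank floor. `shoalwatch` turns such footage into four group-level welfare
indicators used in salmonid aquaculture research:

* **Group cohesion** — the ratio of the area occupied by the main detected
  fish group to the monitored tank area, scored categorically
  (0 = tight, ratio < 0.25; 1 = loose, 0.25 ≤ ratio ≤ 0.75;
  2 = dispersed, ratio > 0.75).
* **Activity** — the mean Euclidean displacement of detected object
  centroids between consecutive frames, weighted by each object's estimated
  fish count:
  `activity = Σ (n̂ᵢ · dᵢ) / Σ n̂ᵢ` over all accepted matches, in cm per
  frame step and cm/s.
* **Enrichment occupation** — the percentage of detected fish pixel area
  lying under a static enrichment structure.
* **Latency to resume normal swimming** after a novel object — the start of
  the first 10 s window in which fewer than 2 distinct fish show darting
  (speed > 3 body lengths/s sustained ≥ 2 frames), right-censored at the
  clip end if the rule is never met.

The measurement chain is: per-pixel median/MAD background model of the
static scene → foreground segmentation by background subtraction →
connected-component detection with intensity-weighted centroids →
single-linkage main-group assignment (minus outliers) → gated
mutual-nearest frame linking → per-clip metrics → tank × week aggregation.

An agent-based simulator (`simulate_school()` + `render_frames()`) generates
synthetic overhead clips of a 1 m tank with full ground truth (positions,
darting flags, hull areas, enrichment dwell), so every stage of the pipeline
is validated by parameter recovery rather than by eye.

## Worked example

Simulate a 20-fish school for one minute, render it, and analyse the clip:

```r
library(shoalwatch)

scene  <- tank_scene()                          # 100 cm tank, lower half monitored
school <- school_params(n_fish = 20, dispersion = 8, seed = 1)
sim    <- simulate_school(scene, school, duration_s = 60, fps = 10)
clip   <- render_frames(sim, noise_sd = 2)

res <- analyse_clip(clip, n_fish_nominal = 20)
res$record[, c("cohesion_ratio", "cohesion_score",
               "activity_cm_per_s", "enrichment_occupation_pct")]
#>   cohesion_ratio cohesion_score activity_cm_per_s enrichment_occupation_pct
#> 1     0.02685526              0          7.451956                  99.36222
```

The school is tightly packed (ratio 0.027 of the monitored area → score 0,
"tight") and sits almost entirely under the 70 cm enrichment footprint,
which the pipeline auto-detected from the background model. At this
dispersion the school is mostly one merged blob, so activity (7.5 cm/s)
reflects blob-level movement; on well-separated schools it recovers the
true per-fish cruising speed within a few percent (see the test suite).
Ground truth from the simulator confirms the occupation:

```r
mean(gt_enrichment_fraction(sim)) * 100   # true % of visible fish under enrichment
#> [1] 99.42171
```

For a novel-object trial, add a stimulus and score the latency:

```r
stim <- stimulus_params(onset_s = 5, initial_dart_rate_per_fish_per_s = 0.4,
                        decay_timescale_s = 10)
sim2 <- simulate_school(scene, school_params(20, dispersion = 64, seed = 3),
                        stimulus = stim, duration_s = 60)
res2 <- analyse_clip(render_frames(sim2, noise_sd = 2),
                     n_fish_nominal = 20, novel_object = TRUE)
res2$latency
#> <latency_result> 25.0 s (51 windows scanned)
```

Darting decays after the stimulus; normal swimming (fewer than 2 darting
fish per 10 s) resumes at 25 s in this clip.

Multi-clip studies are driven by a config (`run_pipeline()`), aggregated
with `aggregate_records()`, and a thin CLI (`exec/shoalwatch`) wraps the
same functions for shell use.

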