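---
title: "Tracking immune-cell migration in microfluidic co-culture devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking immune-cell migration in microfluidic co-culture devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultrack)
```

## The measurement problem

Microfluidic co-culture devices let immune cells and tumor cells share a
chemically connected environment while remaining in distinct compartments: a
wide central chamber holds motile immune cells (here dendritic cells, DCs),
and narrow connecting channels — microgrooves of roughly cell-sized cross
section — lead into collagen-filled side chambers containing cancer cells.
Time-lapse fluorescence recordings of such devices are quantified by
single-particle tracking: each frame is segmented into cell detections, the
detections are linked over time into trajectories, and trajectory-level
statistics summarize how the immune population responds to the tumor
compartments.

`cocultrack` implements this pipeline end to end, together with a synthetic
recording generator, so that every stage — geometry, segmentation, linking,
motility statistics, interaction timing — can be validated against exact
ground truth before it is pointed at real data.

## Device geometry as the coordinate system

The device model is a set of axis-aligned rectangles in micrometres:
a central immune chamber (default 1.2 mm wide), two mirrored arrays of
connecting channels (12 µm wide × 200 µm long footprint, 10 µm high — the
height is metadata, since tracking is 2D), one tumor chamber per side
(500 × 1000 µm footprint, 150 µm deep) and one external medium channel per
side. The x axis is the immune-to-tumor migration axis. Rectangles use
half-open intervals; boundary points between a chamber and a channel belong
to the channel, so the frame at which a trajectory crosses into a channel
is never ambiguous. `rasterize_regions()` paints the same rectangles on the
pixel grid, and the two views agree everywhere except within one pixel of a
rectangle edge, which is the resolution limit of any rasterization.

Analysis is 2D. Cells in these devices move through channels whose height
is close to the cell diameter and through a shallow collagen layer, so the
projected 2D position captures the migration axis; the out-of-plane
dimensions are retained only as metadata.

```{r geometry}
lay <- device_layout(pixel_size = 2)
lay
crossing_boundaries(lay, "right")
```

## The synthetic recording generator

The generator's job is to produce data with *known* structure, not to fit
DC biology. Mobile DC-like agents perform a confined persistent random
walk: each step turns by a wrapped-normal angle (concentration
`persistence`, in 1/rad²) relative to the previous heading, mixed with a
unit drift vector toward a target tumor chamber with weight
`bias_strength` in [0, 1]; step lengths are normal (mean
`speed_mean x frame_interval`, truncated at zero so that speeds are
non-negative — with the default coefficient of variation of 0.3 the
truncation inflates the mean by under 0.1%). Wall collisions reflect;
compartment changes are only possible through the channel openings.
Cancer-cell agents jitter around fixed anchors inside the tumor chambers
and never leave them, emulating collagen-embedded cells.

Two elaborations beyond the minimal model matter in practice:

* **Finite chemokine range.** With a constant whole-chamber drift, every
  biased agent reaches the channels within a few hours and recruitment
  stops — unlike real recordings, where infiltration continues over days.
  When `chemo_range` is finite, the drift weight decays as
  `exp(-d / chemo_range)` with distance `d` from the biased side's channel
  entry line, so recruitment becomes diffusion-limited: agents must random
  walk into the sensing zone before the gradient captures them, spreading
  arrivals over the whole recording.
* **Drift cessation on arrival.** Drift switches off for agents inside the
  target chamber. Without this, all agents converge on a single point of
  the chamber and merge into one fluorescent blob — a degenerate image no
  real device produces; with it, infiltrated agents disperse through the
  chamber in unbiased local motion, as infiltrated DCs are observed to do.

Default parameters are chosen once from the reported biology: mean speed
4 µm/min (measured chamber speeds span 2.0–5.6 µm/min), speed s.d.
1.2 µm/min, persistence 1, 2-min frames, 20 channels per side, agent radii
7 µm (DC) and 9 µm (cancer).

A discretization property worth knowing: sampled positions measure the
*chord* of each inter-frame move, so whenever a step folds against a wall
(reflection), the sampled path undercounts the distance travelled. The
bias grows with step length — a 16 µm step inside a 12 µm channel folds on
almost every frame — which is why the parameter-recovery calibration in
the test suite samples at 0.5-min intervals, where the folding bias is
well below the Monte-Carlo uncertainty, while analysis-scale runs use the
standard 2-min acquisition interval.

Agents render as 2D Gaussian spots (s.d. 0.6 × radius) over a background
offset plus a linear illumination gradient, with Poisson shot noise
(`shot_scale` photons per intensity unit) and optional extra blur. What the
generator does *not* emulate: photobleaching, z-defocus, cell-shape change
during phagocytosis, and brightfield contrast. Tests passing on synthetic
stacks therefore establish the correctness of the measurement chain, not
robustness to every artifact of a specific microscope.

```{r simulate}
cfg <- sim_config(n_dcs = 30, n_cancer_per_chamber = 5, n_frames = 60,
                  bias_strength = 0.8, bias_side = "right", seed = 1)
tracks <- simulate_tracks(cfg, lay)
head(tracks, 3)
```

## Detection

Per frame and fluorescence channel the chain is: restrict to the device
interior (`background_mask()`, layout-driven by default; an image-driven
variant intersects a temporal-variance criterion with the layout), Gaussian
smoothing (`smooth_sigma`, default 1 px), large-scale background
subtraction (`bg_sigma`, default 8 px — removes the offset and slow
gradients), Otsu thresholding on the masked histogram, optional
morphological opening, connected components, an area filter in µm², and
background-subtracted intensity-weighted centroids.

One numerical choice deserves emphasis: Otsu's between-class-variance
criterion silently collapses into the noise mode when spots occupy well
under ~1% of the histogram, which is the normal situation in a sparsely
seeded device. The automatic threshold is therefore floored at
`median + noise_floor_k x MAD` of the masked residual (default k = 6);
pure Otsu is recovered with `noise_floor_k = 0`, and a fixed threshold is
available. Touching cells are not split by default — channel occupancy is
low and the linker's gating tolerates occasional merges.

Region recognition is layout-driven rather than learned from the image: the
chip geometry is known by construction, so the user supplies (or confirms)
the layout and every detection/trajectory point is labelled by
`classify_point()`.

## Linking

Frame-to-frame linking is a minimum-cost one-to-one assignment with squared
displacement as cost, solved exactly by the Hungarian method on the
standard augmented matrix: links farther than `gate_distance` are
infeasible, and leaving a detection unmatched (track birth or death) costs
`gate_distance²`. On instances small enough to enumerate, the solver's
total cost equals the exhaustive minimum over all partial matchings — this
is asserted in the test suite. Track fragments separated by up to
`gap_frames` missing frames are then merged greedily in ascending cost
order when the end-to-start distance is within `gate_distance x gap`,
filling the gap by linear interpolation (flagged per point); finally,
tracks shorter than `min_track_length` are dropped.

The defaults (gate 48 µm ≈ 3 × the expected 2-min step of an 8 µm/min
cell, 2 gap frames, 5-point minimum) are declared configuration, not
inferred constants; every run's manifest records the values used. A
constant-velocity motion prediction is deliberately absent by default:
at these frame rates DC motion is only weakly persistent and the plain
nearest-cost assignment is oracle-verifiable.

## Motility metrics

Per track and per analysis window (half-open, in hours; default 0–24,
24–48, 48–72 h) the package computes:

* **path length** — sum of consecutive Euclidean steps (µm);
* **speed** — path length / duration (µm/min);
* **displacement** — Euclidean start-to-end distance, and separately the
  *horizontal* displacement |Δx| along the migration axis. The two
  conventions answer slightly different questions and the field's usage
  varies, so both are always emitted;
* **directional persistence (DP)** — Euclidean start-to-end distance over
  path length: 1 for a straight monotone path, near 0 for Brownian motion;
* **pre-channel speed** — speed over the points in the immune chamber
  before the track's first channel entry; **post-channel speed** — over the
  points in a tumor chamber after first infiltration. Points inside a
  channel contribute to neither (only the two chamber speeds are defined);
* **migration status** — a track *migrates* when it reaches a channel or
  tumor chamber and *infiltrates* when it reaches a tumor chamber; first
  event frames and the side are recorded, and re-entry into a channel after
  infiltration raises a `reverse_crossing` flag without affecting counts.

Counts per side and window come in two semantics, both emitted by the
pipeline: `event` assigns each cell once to the window of its first
qualifying event; `presence` counts a cell in every window during which it
occupies a qualifying region, which is what image-based counting of cells
in the analysed areas at successive time points measures. Note that
per-window containment (migrating ≥ infiltrated) is only guaranteed under
presence semantics — under event semantics the channel-entry event can fall
in an earlier window than the infiltration event.

A metrics row's `side` is the track's migration side when it migrated,
otherwise the immune-chamber half containing the segment's mean position;
this keeps side-versus-side comparisons defined even for cells that never
leave the chamber.

## Interaction timing

For every DC-cancer pair, maximal runs of frames with centroid distance
within `radius` (default 20 µm = 7 + 9 + 4 µm margin) and the DC inside a
tumor chamber form interaction events; runs separated by at most
`gap_tolerance` frames (default 1, tolerating single missed detections)
are merged. Durations are `(end - start + 1) x frame_interval` minutes.
Distance is centroid-to-centroid; membrane-to-membrane contact would
require segmentation outlines and is out of scope. The radius is a
mandatory, logged configuration entry — there is no universally correct
value, and results should be read as conditional on it.

## Group statistics

Side-versus-side comparisons use the classical unpaired two-sample t-test
in the equal-variance (Student) form, two-sided, significant at p ≤ 0.05;
Welch's form is available behind a flag. Summaries report per-cell n;
cell-level and experiment-level dispersion answer different questions, and
the run bundle retains the per-track table so either can be computed.

## The standard benchmark recording

`standard_fixture_config()` defines the package's reference experiment:
100 DCs, 72 h at 2-min intervals, bias 0.8 toward the right chamber with a
300 µm sensing range, no bias on the left, 15 cancer cells per chamber,
seed-controlled. The ground truth is simulated at full temporal resolution
(2160 frames); for the image-analysis stages it is downsampled to 10-min
frames (432 frames) and rendered at 4 µm/px (≈ 750 × 300 px). These sizes
were chosen so a complete render-detect-link-measure cycle stays at
desk scale while inter-frame motion (≤ ~50 µm) remains well inside the
linking gate. On this fixture the pipeline must report more migrating and
more infiltrated cells on the biased side in every window (presence
counts) and a higher mean DP on the biased side, per window and pooled.
The unbiased-side cohort shrinks sharply in the late windows — the same
asymmetry decay seen in real competition experiments — so the pooled DP
comparison is the statistically stable statement; the per-window one is
asserted at the benchmark's fixed seed.

## Known limitations

* Touching cells are merged, not split; dense aggregates are undercounted.
* No mitosis or split/merge handling in the linker.
* Counts are track-based; fragmented tracks can double-count a cell's
  events across windows (they cannot within a window).
* The simulator's motion model is a means of producing controlled ground
  truth; its parameters are not fitted to any particular cell type, and
  the presets should not be read as a biological model of DC chemotaxis.
* 3D (z-resolved) tracking is out of scope by design.
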