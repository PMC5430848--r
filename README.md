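# cocultrack

Unsupervised single-particle tracking and motility analysis for time-lapse
fluorescence recordings of microfluidic immune–tumor co-cultures.

## The problem

In two-sided microfluidic co-culture devices, motile immune cells (e.g.
dendritic cells, DCs) sit in a wide central chamber and can reach
collagen-embedded cancer cells in two lateral tumor chambers only through
arrays of narrow connecting channels (~12 µm wide, 200 µm long). Time-lapse
recordings of such devices answer questions like: how many immune cells
migrate toward each tumor compartment, how fast do they move before and
after crossing the channels, how directed is their motion, and how long do
they dwell in contact with individual cancer cells?

`cocultrack` turns a calibrated image stack plus a parametric description of
the device into those read-outs via the classical three-step tracking
algorithm — background elimination (restriction to the device interior),
per-frame cell segmentation, and frame-to-frame linking — followed by
compartment-aware trajectory statistics. A synthetic-recording generator
(confined biased persistent random walks rendered as noisy fluorescence
movies) provides exact ground truth so every stage is testable.

## The quantities

For a trajectory sampled at positions $p_0, \dots, p_n$ (µm) every
$\Delta t$ minutes:

* path length $L = \sum_i \lVert p_{i+1} - p_i \rVert$ (µm);
* speed $v = L / (n\,\Delta t)$ (µm/min) — total distance travelled over
  the duration of migration; *pre-channel* speed restricts to the points in
  the immune chamber before first channel entry, *post-channel* speed to
  the points in a tumor chamber after first infiltration;
* displacement — Euclidean $\lVert p_n - p_0 \rVert$ and horizontal
  $|x_n - x_0|$ along the immune→tumor axis (both emitted);
* directional persistence $\mathrm{DP} = \lVert p_n - p_0 \rVert / L
  \in [0, 1]$: 1 = straight path, ≈0 = Brownian motion;
* migrating / infiltrated counts per side and per analysis window
  (default 0–24, 24–48, 48–72 h), in first-event and presence semantics;
* interaction time: duration (min) a DC centroid stays within a circular
  region of interaction (default radius 20 µm) around a cancer cell;
* side-vs-side comparisons with the two-tailed unpaired Student's t-test.

Linking is an exact minimum-cost assignment (Hungarian method) with squared
displacement costs, a hard distance gate, gap closing, and a minimum track
length — all configurable and recorded in the run manifest.

## Worked example

A synthetic recording with a chemotactic bias toward the right tumor
chamber, run end to end:

```r
library(cocultrack)

cfg <- run_config(
  out_dir  = "demo_run",
  layout   = list(pixel_size = 4),
  simulate = list(n_dcs = 12, n_cancer_per_chamber = 4, n_frames = 90,
                  speed_mean = 5, bias_strength = 0.9, bias_side = "right",
                  noise = list(background = 0.05, gradient = 0.01,
                               shot_scale = 2000)),
  detection = detect_params(smooth_sigma = 1, min_area = 20, max_area = 4000),
  linking   = link_params(gate_distance = 40, min_track_length = 5),
  windows   = window_spec(rbind(c(0, 3)), min_frames_in_window = 5),
  seed      = 11)
res <- run_pipeline(cfg)
res$counts_presence
#> # A tibble: 2 × 4
#>   side  window migrating infiltrated
#>   <chr> <chr>      <int>       <int>
#> 1 left  0-3h           0           0
#> 2 right 0-3h           4           3
head(res$metrics[, c("track_id", "side", "dp", "speed", "migrated")], 4)
#> # A tibble: 4 × 5
#>   track_id side     dp speed migrated
#>      <dbl> <chr> <dbl> <dbl> <lgl>
#> 1        9 left  0.997  5.19 FALSE
#> 2       10 left  0.997  5.21 FALSE
#> 3       11 left  0.997  4.89 FALSE
#> 4       12 left  0.998  5.14 FALSE
```

Within the first three hours, 4 of the 12 DCs have entered the channels
toward the biased right side and 3 have reached the tumor chamber; no cell
moved toward the unbiased left side. Each metrics row is one track in one
window: with `bias_strength = 0.9` every path is almost straight
(`dp` ≈ 1, even for left-half cells that have not yet reached a channel),
and `speed` (µm/min) recovers the configured 5 µm/min. All tables are also
written as CSVs under `out_dir`, next to a manifest recording every
materialized parameter.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/cocultrack.R simulate --config run.yml   # TIFFs + truth
Rscript inst/cli/cocultrack.R run      --config run.yml   # full analysis
```

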